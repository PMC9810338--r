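# shared fixtures built in code at test time

# noiseless ACF curve generated from a model function on a log grid
noiseless_acf <- function(model = c("anomalous", "ou"), params,
                          lags = 10^seq(-6, 0, length.out = 80)) {
  model <- match.arg(model)
  vals <- if (model == "anomalous") {
    do.call(acf_anomalous, c(list(tau = lags), params))
  } else {
    do.call(acf_ou, c(list(tau = lags), params))
  }
  acf_curve(lags, vals)
}

# standard small confined-Brownian acquisition (fast enough for unit tests)
small_brownian_config <- function(seed, D = 10, d = 0.85, duration = 4,
                                  dt = 1e-5, n_particles = 50, ...) {
  simulation_config(n_particles = n_particles, dt = dt, duration = duration,
                    geometry = cell_geometry(5, d),
                    motion = motion_model("brownian", D = D),
                    seed = seed, ...)
}

# two-state telegraph intensity (rate k each way); analytic ACF ~ exp(-2 k t)
telegraph_trace <- function(n, dt, k, seed) {
  set.seed(seed)
  flips <- stats::runif(n) < k * dt
  state <- as.numeric(cumsum(c(1L, flips[-1])) %% 2L == 0L)
  intensity_trace(state + 0.5, dt) # offset keeps the mean well above zero
}
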