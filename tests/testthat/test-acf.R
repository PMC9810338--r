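test_that("ACF of a constant trace is zero and zero traces are rejected", {
  tr <- intensity_trace(rep(3, 5000), 1e-4)
  a <- compute_acf(tr)
  expect_equal(a$values, rep(0, length(a$lags)))
  expect_error(compute_acf(intensity_trace(rep(0, 5000), 1e-4)),
               "all-zero")
})

test_that("symmetric normalization makes the ACF scale invariant", {
  set.seed(5)
  tr <- intensity_trace(rexp(20000, 1), 1e-4)
  a1 <- compute_acf(tr)
  a2 <- compute_acf(intensity_trace(tr$values * 137.5, 1e-4))
  expect_equal(a1$values, a2$values, tolerance = 1e-9)
})

test_that("shot noise on an immobile emitter is uncorrelated at all lags", {
  set.seed(6)
  n <- 2e5
  tr <- intensity_trace(rpois(n, 5), 1e-5)
  a <- compute_acf(tr)
  pos <- a$lags > 0
  # white noise: per-lag estimator sd ~ 1/(mean^2 sqrt(n))
  se <- 1 / (5 * sqrt(n))
  expect_true(all(abs(a$values[pos]) < 3.5 * se))
})

test_that("telegraph intensity decorrelates at the analytic rate 2k", {
  k <- 20
  dt <- 1e-4
  tr <- telegraph_trace(8e5, dt, k, seed = 8)
  a <- compute_acf(tr, max_lag = 0.1)
  # amplitude + rate fit on the linear scale (log-fits overweight the
  # noise-dominated tail)
  fit <- minpack.lm::nlsLM(v ~ A * exp(-r * l),
                           data = list(v = a$values, l = a$lags),
                           start = list(A = 0.25, r = 30))
  expect_equal(unname(coef(fit)["r"]), 2 * k, tolerance = 0.05)
})

test_that("blinking multiplier equals the model blinking term exactly", {
  lags <- 10^seq(-6, -1, length.out = 40)
  a <- acf_curve(lags, rep(1, 40))
  b <- apply_blinking_factor(a)
  expect_equal(b$values[1], 1 + (0.1 / 1.1) * exp(-lags[1] / 25e-6))
  expect_equal(b$values, blinking_term(lags, F_P = 1 / 12, tau_P = 25e-6))
  expect_equal(b$values[40], 1, tolerance = 1e-12) # long-lag limit
})

test_that("average_acf pools replicate curves with per-lag SEM", {
  lags <- 10^seq(-5, -1, length.out = 20)
  curves <- lapply(1:4, function(i) acf_curve(lags, rep(i, 20)))
  m <- average_acf(curves)
  expect_equal(m$values, rep(2.5, 20))
  expect_equal(m$sem, rep(sd(1:4) / 2, 20))
  expect_error(average_acf(list(curves[[1]],
                                acf_curve(lags * 2, rep(1, 20)))))
})

test_that("detrending leaves a stationary trace essentially unchanged", {
  set.seed(10)
  x <- 50 + rnorm(40000)
  tr <- intensity_trace(x, 1e-4)
  out <- detrend_trace(tr)
  expect_equal(out$values, tr$values, tolerance = 0.01)
  expect_equal(mean(out$values), mean(x), tolerance = 0.01)
})

test_that("a linear bleaching ramp is flattened by orders of magnitude", {
  set.seed(11)
  n <- 50000
  tt <- seq_len(n) / n
  x <- (1 - 0.1 * tt) * 40 + rnorm(n, sd = 0.5)
  tr <- intensity_trace(x, 1e-4)
  out <- detrend_trace(tr)
  b0 <- coef(lm(x ~ tt))[2]
  b1 <- coef(lm(out$values ~ tt))[2]
  expect_lt(abs(b1), 0.01 * abs(b0))
  # mean of the corrected trace matches the initial level f(0) within 1%
  trend0 <- 40
  expect_equal(mean(out$values), trend0, tolerance = 0.01)
})

test_that("detrending is idempotent at the ACF level", {
  set.seed(12)
  n <- 60000
  tt <- seq_len(n) / n
  x <- exp(-0.15 * tt) * 30 + rnorm(n, sd = 1)
  tr <- intensity_trace(x, 1e-4)
  d1 <- detrend_trace(tr)
  d2 <- detrend_trace(d1)
  a1 <- compute_acf(d1, min_lag = 1e-3)
  a2 <- compute_acf(d2, min_lag = 1e-3)
  denom <- max(abs(a1$values))
  expect_lt(max(abs(a1$values - a2$values)) / denom, 0.01)
})

test_that("detrending restores the bleach-free ACF of a matched simulation", {
  # paired seeds: trajectories are identical until an emitter bleaches;
  # bleach rate gives ~15% intensity loss over each 20-s acquisition
  pairs <- lapply(c(31, 131, 231), function(s) {
    base <- small_brownian_config(seed = s, duration = 20)
    bl <- base
    bl$bleach_rate <- 0.2
    tr1 <- simulate_trace(bl)
    loss <- 1 - mean(tail(tr1$values, 2e5)) / mean(head(tr1$values, 2e5))
    expect_gt(loss, 0.05) # the bleaching plumbing is actually doing something
    list(clean = compute_acf(simulate_trace(base), min_lag = 1e-4,
                             max_lag = 0.01),
         corr = compute_acf(detrend_trace(tr1), min_lag = 1e-4,
                            max_lag = 0.01))
  })
  a0 <- average_acf(lapply(pairs, `[[`, "clean"))
  a1 <- average_acf(lapply(pairs, `[[`, "corr"))
  # tau_D = w0^2/(4D) = 1 ms; compare lags below 10 tau_D
  expect_lt(max(abs(a1$values - a0$values)) / max(a0$values), 0.10)
})

test_that("nonpositive fitted trends are rejected", {
  n <- 20000
  x <- seq(10, -5, length.out = n) # crosses zero
  expect_error(detrend_trace(intensity_trace(pmax(x, 0), 1e-4)),
               "nonpositive")
})
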