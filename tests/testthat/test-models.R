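test_that("blinking term has the right limits and the 0.1/1.1 identity", {
  tau <- 10^seq(-7, 0, length.out = 50)
  expect_equal(blinking_term(tau, 0), rep(1, 50))
  expect_equal(blinking_term(0, 0.2), 1 / 0.8)
  # dark fraction 1/12 is exactly the 1 + 0.1 exp(-t/tauH) / 1.1 multiplier
  expect_equal(blinking_term(tau, 1 / 12, 25e-6),
               1 + (0.1 / 1.1) * exp(-tau / 25e-6))
  expect_error(blinking_term(1e-4, 1))
})

test_that("anomalous model matches hand-evaluated anchor points", {
  expect_equal(acf_anomalous(1e-12, N = 2, tau_D = 1e-3, alpha = 0.8), 0.5,
               tolerance = 1e-6)
  # at tau = tau_D the alpha dependence cancels: 0.5 / sqrt(1 + 1/64)
  for (a in c(0.5, 0.85, 1)) {
    expect_equal(acf_anomalous(1e-3, N = 1, tau_D = 1e-3, alpha = a, S = 8),
                 0.5 / sqrt(1 + 1 / 64))
  }
  expect_error(acf_anomalous(1e-3, N = 1, tau_D = -1))
})

test_that("OU model has the correct amplitude and anchor value", {
  # E(0) = 0: amplitude G_inf + 1/N
  expect_equal(acf_ou(0, N = 4, D = 10, sigma = 0.42, G_inf = 0.01),
               0.01 + 0.25)
  # frozen independent evaluation of the three factors at tau = tau_D,
  # omega0 = 0.19, sigma = 0.42, S = 8 (computed term by term by hand)
  tau_D <- 0.19^2 / (4 * 10)
  expect_equal(acf_ou(tau_D, N = 1, D = 10, sigma = 0.42, omega0 = 0.19,
                      S = 8), 0.508, tolerance = 1e-3)
  expect_error(acf_ou(1e-3, N = 1, D = 10, sigma = -1))
})

test_that("OU model reduces to the unconfined Brownian model as sigma grows", {
  tau <- 10^seq(-6, 1, length.out = 200) # seven decades of lag
  w0 <- 0.19
  D <- 8
  tau_D <- w0^2 / (4 * D)
  ou <- acf_ou(tau, N = 1.7, D = D, sigma = 1e7 * w0, omega0 = w0, S = 8,
               F_P = 0.1, G_inf = 2e-3)
  br <- acf_anomalous(tau, N = 1.7, tau_D = tau_D, alpha = 1, S = 8,
                      F_P = 0.1, G_inf = 2e-3)
  expect_lt(max(abs(ou - br) / br), 1e-9)
})

test_that("models decay monotonically to G_inf and amplitude is 1/(N(1-F_P))", {
  tau <- 10^seq(-7, 1, length.out = 300)
  an <- acf_anomalous(tau, N = 2, tau_D = 8e-4, alpha = 0.85, S = 8,
                      G_inf = 0.01)
  ou <- acf_ou(tau, N = 2, D = 10, sigma = 0.42, G_inf = 0.01)
  expect_true(all(diff(an) < 0))
  expect_true(all(diff(ou) < 0))
  # long-lag convergence to the offset
  expect_lt(an[length(an)] - 0.01, 1e-4)
  expect_gt(an[length(an)], 0.01)
  # zero-lag amplitude above offset, including blinking
  expect_equal(acf_anomalous(0, N = 2, tau_D = 8e-4, alpha = 0.9,
                             F_P = 0.2) , 1 / (2 * 0.8))
  expect_equal(acf_ou(0, N = 2, D = 10, sigma = 0.4, F_P = 0.2),
               1 / (2 * 0.8))
})

test_that("stronger confinement slows the OU decorrelation pointwise", {
  # suppressing fluctuations across the confined axes raises the ACF: at any
  # fixed lag the model is non-increasing in the confinement width sigma
  tau <- 10^seq(-5, 0, length.out = 60)
  sig <- c(0.2, 0.3, 0.42, 0.6, 1, 5)
  g <- sapply(sig, function(s) acf_ou(tau, N = 1, D = 10, sigma = s))
  expect_true(all(apply(g, 1, diff) < 1e-12))
  # consequence: a fit with sigma too small needs a larger D to match data
})

test_that("diffusion time converts to D per the beam-transit relation", {
  # calibration: tau_D = 20.9 us with D = 414 um^2/s gives the 0.186 um waist
  expect_equal(sqrt(4 * 414 * 20.9e-6), 0.186, tolerance = 5e-4)
  expect_equal(tau_to_D(20.9e-6, 0.1860387), 414, tolerance = 1e-4)
  expect_equal(tau_to_D(1e-3, 0.2), 10)
  x <- c(1e-4, 7e-3); w <- 0.19
  expect_equal(D_to_tau(tau_to_D(x, w), w), x)
  expect_error(tau_to_D(-1, 0.2))
  expect_error(D_to_tau(10, 0))
})

test_that("two-component model interpolates its single-species limits", {
  tau <- 10^seq(-6, 0, length.out = 50)
  one_fast <- acf_anomalous(tau, N = 3, tau_D = 561e-6, alpha = 0.86,
                            F_P = 0.1)
  one_slow <- acf_anomalous(tau, N = 3, tau_D = 1100e-6, alpha = 0.88,
                            F_P = 0.1)
  expect_equal(acf_two_component(tau, N = 3, w = 1, 561e-6, 0.86,
                                 1100e-6, 0.88, F_P = 0.1), one_fast)
  expect_equal(acf_two_component(tau, N = 3, w = 0, 561e-6, 0.86,
                                 1100e-6, 0.88, F_P = 0.1), one_slow)
  mid <- acf_two_component(tau, N = 3, w = 0.5, 561e-6, 0.86, 1100e-6, 0.88,
                           F_P = 0.1)
  expect_true(all(mid >= pmin(one_fast, one_slow) - 1e-15 &
                    mid <= pmax(one_fast, one_slow) + 1e-15))
})
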