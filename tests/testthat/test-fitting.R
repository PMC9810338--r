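test_that("noiseless anomalous curves are recovered to 1e-6 relative", {
  truth <- list(N = 5, tau_D = 800e-6, alpha = 0.85, F_P = 0.1,
                tau_P = 25e-6, S = 8, G_inf = 0.002)
  a <- noiseless_acf("anomalous", truth)
  fit <- fit_acf(a, "anomalous")
  expect_true(fit$converged)
  for (p in c("N", "tau_D", "alpha", "F_P", "G_inf")) {
    expect_equal(fit$par[[p]], truth[[p]], tolerance = 1e-6)
  }
  expect_lt(fit$ssr, 1e-16)
})

test_that("noiseless OU curves are recovered to 1e-6 relative", {
  truth <- list(N = 2, D = 12, sigma = 0.42, omega0 = 0.19, F_P = 0.08,
                tau_P = 25e-6, S = 8, G_inf = 0.001)
  a <- noiseless_acf("ou", truth)
  fit <- fit_acf(a, "ou")
  expect_true(fit$converged)
  for (p in c("N", "D", "F_P", "G_inf")) {
    expect_equal(fit$par[[p]], truth[[p]], tolerance = 1e-6)
  }
})

test_that("short curves and narrow lag spans are rejected", {
  lags <- 10^seq(-4, -3.5, length.out = 30)
  expect_error(fit_acf(acf_curve(lags, rep(1, 30)), "anomalous"), "decades")
  lags2 <- 10^seq(-6, 0, length.out = 5)
  expect_error(fit_acf(acf_curve(lags2, rep(1, 5)), "anomalous"), "10 points")
})

test_that("max_lag restricts the fitted window", {
  truth <- list(N = 5, tau_D = 800e-6, alpha = 0.85, F_P = 0, tau_P = 25e-6,
                S = 8, G_inf = 0)
  a <- noiseless_acf("anomalous", truth)
  fit <- fit_acf(a, "anomalous", fixed = list(F_P = 0), max_lag = 1e-2)
  expect_true(all(fit$lags <= 1e-2))
  expect_equal(fit$par$tau_D, truth$tau_D, tolerance = 1e-5)
})

test_that("two-component fit recovers the slow species with the fast fixed", {
  lags <- 10^seq(-6, 0, length.out = 90)
  truth <- list(N = 3, w = 0.15, tau_D_fast = 561e-6, alpha_fast = 0.86,
                tau_D_slow = 1100e-6, alpha_slow = 0.88, F_P = 0.1,
                G_inf = 0.001)
  vals <- acf_two_component(lags, truth$N, truth$w, truth$tau_D_fast,
                            truth$alpha_fast, truth$tau_D_slow,
                            truth$alpha_slow, F_P = truth$F_P,
                            G_inf = truth$G_inf)
  a <- acf_curve(lags, vals)
  fit <- fit_two_component(a, fast = list(w = 0.15, tau_D = 561e-6,
                                          alpha = 0.86))
  expect_equal(fit$par$tau_D_slow, truth$tau_D_slow, tolerance = 0.02)
  expect_equal(fit$par$alpha_slow, truth$alpha_slow, tolerance = 0.02)
})

test_that("degenerate two-component weights reduce to single-species fits", {
  lags <- 10^seq(-6, 0, length.out = 80)
  single <- acf_anomalous(lags, N = 4, tau_D = 900e-6, alpha = 0.84,
                          F_P = 0.05)
  a <- acf_curve(lags, single)
  # w = 0: fast species irrelevant, slow fitted
  f0 <- fit_two_component(a, fast = list(w = 0, tau_D = 1e-4, alpha = 1))
  expect_equal(f0$par$tau_D_slow, 900e-6, tolerance = 1e-4)
  expect_equal(f0$par$alpha_slow, 0.84, tolerance = 1e-4)
  # w = 1: the fitted curve equals the fast single-species model
  f1 <- fit_two_component(a, fast = list(w = 1, tau_D = 900e-6,
                                         alpha = 0.84))
  expect_equal(f1$fitted, single, tolerance = 1e-4)
})

test_that("per-cell aggregation averages converged acquisitions only", {
  mk <- function(tau_D, converged = TRUE) {
    structure(list(model = "anomalous",
                   par = list(tau_D = tau_D, alpha = 0.85),
                   converged = converged), class = "fcs_fit")
  }
  fits <- lapply(c(500, 520, 540, 560, 580, 600) * 1e-6, mk)
  m <- aggregate_cell(fits)
  expect_equal(m$tau_D$mean, 550e-6)
  expect_equal(m$tau_D$sem, sd(c(500, 520, 540, 560, 580, 600) * 1e-6) /
                 sqrt(6))
  expect_equal(m$tau_D$sem, 15.28e-6, tolerance = 1e-3)
  # identical fits: zero SEM
  m2 <- aggregate_cell(lapply(rep(550e-6, 6), mk))
  expect_equal(m2$tau_D$sem, 0)
  # one non-converged fit is excluded from the average
  fits[[6]] <- mk(10, converged = FALSE)
  m3 <- aggregate_cell(fits)
  expect_equal(m3$n_converged, 5)
  expect_equal(m3$tau_D$mean, mean(c(500, 520, 540, 560, 580) * 1e-6))
  expect_error(aggregate_cell(list(mk(1e-3, converged = FALSE))),
               "no converged")
})

test_that("model comparison ranks by AIC and respects nesting", {
  truth <- list(N = 2, tau_D = 1e-3, alpha = 0.8, F_P = 0.05, tau_P = 25e-6,
                S = 8, G_inf = 0)
  a <- noiseless_acf("anomalous", truth)
  tab <- compare_models(a, models = c("brownian", "anomalous"))
  expect_equal(tab$model[1], "anomalous")
  br <- tab[tab$model == "brownian", ]
  an <- tab[tab$model == "anomalous", ]
  expect_lte(an$ssr, br$ssr) # brownian is nested in anomalous
  # the OU model carries one less free parameter than the anomalous model
  tab2 <- compare_models(a, models = c("anomalous", "ou"))
  expect_equal(tab2$n_free[tab2$model == "ou"],
               tab2$n_free[tab2$model == "anomalous"] - 1)
})

test_that("Welch test matches the reference implementation and conventions", {
  x <- c(14.7, 14.2, 15.1, 14.9, 13.8)
  y <- c(12.9, 13.4, 12.1, 13.9, 12.6, 13.0)
  mine <- welch_t_test(x, y)
  ref <- t.test(x, y, var.equal = FALSE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$dof, unname(ref$parameter), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  same <- welch_t_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Welch test holds its nominal type-I error under the null", {
  set.seed(33)
  reps <- 4000 # binomial sd ~ 0.0034, so the 0.015 band is ~4.4 sigma
  p <- replicate(reps, welch_t_test(rnorm(20, 14.7, 2), rnorm(20, 14.7, 2))$p)
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 0.015)
})
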