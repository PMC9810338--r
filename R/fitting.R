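#' @importFrom Rcpp sourceCpp
#' @useDynLib confinedfcs, .registration = TRUE
NULL

# full parameter sets and defaults per model; `fixed_default` mirrors the
# experimental fitting conventions (tau_P = 25 us, S = 8; OU additionally
# omega0 = 0.19 um, sigma = d/2 = 0.42 um)
model_spec <- function(model) {
  switch(model,
    anomalous = list(
      params = c("N", "tau_D", "alpha", "F_P", "tau_P", "S", "G_inf"),
      fixed_default = list(tau_P = 25e-6, S = 8),
      eval = function(tau, p) acf_anomalous(tau, p$N, p$tau_D, p$alpha,
                                            p$F_P, p$tau_P, p$S, p$G_inf)),
    brownian = list(
      params = c("N", "tau_D", "alpha", "F_P", "tau_P", "S", "G_inf"),
      fixed_default = list(tau_P = 25e-6, S = 8, alpha = 1),
      eval = function(tau, p) acf_anomalous(tau, p$N, p$tau_D, p$alpha,
                                            p$F_P, p$tau_P, p$S, p$G_inf)),
    ou = list(
      params = c("N", "D", "sigma", "omega0", "F_P", "tau_P", "S", "G_inf"),
      fixed_default = list(tau_P = 25e-6, S = 8, omega0 = 0.19, sigma = 0.42),
      eval = function(tau, p) acf_ou(tau, p$N, p$D, p$sigma, p$omega0,
                                     p$F_P, p$tau_P, p$S, p$G_inf)),
    stop("unknown model: ", model)
  )
}

default_bounds <- list(
  N = c(1e-4, Inf), tau_D = c(1e-8, 100), alpha = c(0.3, 1.3),
  F_P = c(0, 0.5), tau_P = c(1e-7, 1e-2), S = c(1, 100),
  G_inf = c(-Inf, Inf), D = c(1e-4, 1e5), sigma = c(1e-3, 1e3),
  omega0 = c(1e-3, 10)
)

# data-driven starting values: amplitude from the first lags, tau_D from the
# half-amplitude lag, alpha = 0.85, F_P = 0.1
default_init <- function(acf, model, fixed) {
  g0 <- max(mean(acf$values[seq_len(min(3, length(acf$values)))]), 1e-6)
  g_inf0 <- mean(utils::tail(acf$values, max(2, length(acf$values) %/% 10)))
  amp <- max(g0 - g_inf0, 1e-6)
  half_idx <- which(acf$values - g_inf0 <= amp / 2)
  tau_half <- if (length(half_idx) > 0) acf$lags[half_idx[1]] else
    stats::median(acf$lags)
  init <- list(N = 1 / amp, tau_D = tau_half, alpha = 0.85, F_P = 0.1,
               G_inf = 0)
  if (model == "ou") {
    w0 <- if (!is.null(fixed$omega0)) fixed$omega0 else 0.19
    init$D <- tau_to_D(tau_half, w0)
  }
  init
}

#' Fit an ACF curve with a diffusion model
#'
#' Nonlinear least squares (Levenberg-Marquardt, via \pkg{minpack.lm}) of one
#' of the registered models: `"anomalous"` (free `N, tau_D, alpha, F_P,
#' G_inf`; fixed `tau_P = 25e-6 s, S = 8`), `"brownian"` (anomalous with
#' `alpha` fixed to 1), or `"ou"` (free `N, D, F_P, G_inf`; fixed `tau_P, S,
#' omega0 = 0.19 um, sigma = 0.42 um`). Entries of `fixed` override or extend
#' the per-model fixed set; any model parameter not fixed is fitted.
#'
#' @param acf An [acf_curve()].
#' @param model `"anomalous"`, `"ou"` or `"brownian"`.
#' @param fixed Named list of parameters to hold fixed (values included).
#' @param init Named list overriding the data-driven starting values.
#' @param lower,upper Named lists overriding default box constraints
#'   (`alpha` in `[0.3, 1.3]`, `F_P` in `[0, 0.5]`).
#' @param weights `NULL` (unweighted, the default), `"sem"` (1/sem^2 using
#'   the curve's per-lag dispersion), or a numeric vector.
#' @param max_lag Optional upper lag cutoff (s) for short-lag-window refits.
#' @return An object of class `fcs_fit`: full parameter list `par`, fitted
#'   values + standard errors, `ssr`, `aic`, `converged`, `at_bounds`.
#' @export
fit_acf <- function(acf, model = c("anomalous", "ou", "brownian"),
                    fixed = list(), init = list(), lower = list(),
                    upper = list(), weights = NULL, max_lag = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(acf, "acf_curve"))
  if (!is.null(max_lag)) {
    keep <- acf$lags <= max_lag
    acf <- acf_curve(acf$lags[keep], acf$values[keep],
                     sem = if (!is.null(acf$sem)) acf$sem[keep],
                     min_lag = acf$min_lag)
  }
  n <- length(acf$lags)
  if (n < 10 || log10(max(acf$lags) / min(acf$lags)) < 2) {
    stop("ACF must have >= 10 points spanning >= 2 decades")
  }
  spec <- model_spec(model)
  fixed_all <- utils::modifyList(spec$fixed_default, fixed)
  free_names <- setdiff(spec$params, names(fixed_all))
  init_all <- utils::modifyList(default_init(acf, model, fixed_all), init)
  start <- unlist(init_all[free_names])
  lo <- sapply(free_names, function(p)
    if (!is.null(lower[[p]])) lower[[p]] else default_bounds[[p]][1])
  hi <- sapply(free_names, function(p)
    if (!is.null(upper[[p]])) upper[[p]] else default_bounds[[p]][2])
  start <- pmin(pmax(start, lo), hi)
  w <- if (is.null(weights)) rep(1, n)
  else if (identical(weights, "sem")) {
    if (is.null(acf$sem)) stop("curve carries no sem")
    1 / pmax(acf$sem, 1e-12)^2
  } else as.numeric(weights)
  sw <- sqrt(w)
  resid_fn <- function(theta) {
    p <- c(as.list(theta), fixed_all)
    names(p)[seq_along(theta)] <- free_names
    sw * (spec$eval(acf$lags, p) - acf$values)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- fit$par
  names(est) <- free_names
  ssr <- sum(fit$fvec^2)
  k <- length(est)
  se <- rep(NA_real_, k)
  names(se) <- free_names
  cov_ok <- tryCatch({
    hess <- fit$hessian
    cv <- chol2inv(chol(hess)) * ssr / max(n - k, 1)
    se[] <- sqrt(diag(cv))
    TRUE
  }, error = function(e) FALSE)
  at_bounds <- free_names[est <= lo + 1e-12 * pmax(abs(lo), 1) & is.finite(lo) |
                            est >= hi - 1e-12 * pmax(abs(hi), 1) & is.finite(hi)]
  # drop F_P "at bound" at exactly 0: a zero dark fraction is interior science
  at_bounds <- setdiff(at_bounds, if (isTRUE(est["F_P"] == 0)) "F_P")
  par <- c(as.list(est), fixed_all)
  structure(list(model = model, par = par, free = est, se = se,
                 fixed = fixed_all, ssr = ssr, n_points = n, n_free = k,
                 converged = fit$info %in% 1:3, info = fit$info,
                 aic = n * log(ssr / n) + 2 * (k + 1),
                 at_bounds = at_bounds, cov_ok = cov_ok,
                 lags = acf$lags,
                 fitted = spec$eval(acf$lags, par),
                 residuals = spec$eval(acf$lags, par) - acf$values),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS fit (", x$model, "), ", x$n_points, " lags, ssr = ",
      signif(x$ssr, 4), if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  est <- cbind(estimate = x$free, se = x$se)
  print(signif(est, 4))
  invisible(x)
}

#' Two-component anomalous fit with a fixed fast species
#'
#' Fits [acf_two_component()] with the fast component fully specified
#' (weight, `tau_D`, `alpha`) and the slow component free, as in the control
#' for a contaminating free-fluorophore fraction. Free parameters:
#' `N, F_P, tau_D_slow, alpha_slow, G_inf`.
#'
#' @param acf An [acf_curve()].
#' @param fast List with `w`, `tau_D`, `alpha` of the fixed fast species.
#' @param fixed Named list of additional fixed parameters
#'   (default `tau_P = 25e-6`, `S = 8`).
#' @param init,lower,upper,weights As in [fit_acf()].
#' @return An `fcs_fit` with model `"two_component"`.
#' @export
fit_two_component <- function(acf, fast, fixed = list(), init = list(),
                              lower = list(), upper = list(),
                              weights = NULL) {
  stopifnot(inherits(acf, "acf_curve"),
            all(c("w", "tau_D", "alpha") %in% names(fast)))
  fixed_all <- utils::modifyList(list(tau_P = 25e-6, S = 8), fixed)
  free_names <- setdiff(c("N", "tau_D_slow", "alpha_slow", "F_P", "G_inf"),
                        names(fixed_all))
  ini <- default_init(acf, "anomalous", fixed_all)
  init_all <- utils::modifyList(
    list(N = ini$N, tau_D_slow = ini$tau_D, alpha_slow = 0.85, F_P = 0.1,
         G_inf = 0), init)
  bnd <- function(p) {
    base <- sub("_slow$", "", p)
    default_bounds[[base]]
  }
  lo <- sapply(free_names, function(p)
    if (!is.null(lower[[p]])) lower[[p]] else bnd(p)[1])
  hi <- sapply(free_names, function(p)
    if (!is.null(upper[[p]])) upper[[p]] else bnd(p)[2])
  start <- pmin(pmax(unlist(init_all[free_names]), lo), hi)
  n <- length(acf$lags)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  sw <- sqrt(w)
  eval2 <- function(tau, p) {
    acf_two_component(tau, p$N, fast$w, fast$tau_D, fast$alpha,
                      p$tau_D_slow, p$alpha_slow, p$F_P, p$tau_P, p$S,
                      p$G_inf)
  }
  resid_fn <- function(theta) {
    p <- c(as.list(theta), fixed_all)
    names(p)[seq_along(theta)] <- free_names
    sw * (eval2(acf$lags, p) - acf$values)
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = lo, upper = hi, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- fit$par
  names(est) <- free_names
  ssr <- sum(fit$fvec^2)
  se <- rep(NA_real_, length(est))
  names(se) <- free_names
  tryCatch({
    cv <- chol2inv(chol(fit$hessian)) * ssr / max(n - length(est), 1)
    se[] <- sqrt(diag(cv))
  }, error = function(e) NULL)
  par <- c(as.list(est), fixed_all, list(fast = fast))
  structure(list(model = "two_component", par = par, free = est, se = se,
                 fixed = fixed_all, ssr = ssr, n_points = n,
                 n_free = length(est), converged = fit$info %in% 1:3,
                 info = fit$info,
                 aic = n * log(ssr / n) + 2 * (length(est) + 1),
                 at_bounds = character(0), lags = acf$lags,
                 fitted = eval2(acf$lags, par)),
            class = "fcs_fit")
}

#' Aggregate per-acquisition fits into a per-cell measurement
#'
#' Arithmetic mean and SEM of the mobility parameters over the converged
#' fits of the (typically six) sequential acquisitions on one cell.
#'
#' @param fits List of `fcs_fit` objects from the same model.
#' @return Object of class `cell_measurement`: `n_total`, `n_converged`, and
#'   per-parameter `mean`/`sem` for `tau_D` and `alpha` (anomalous-family
#'   fits) or `D` (OU fits).
#' @export
aggregate_cell <- function(fits) {
  stopifnot(length(fits) >= 1, all(sapply(fits, inherits, "fcs_fit")))
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(ok) == 0) stop("no converged fits to aggregate")
  grab <- function(name) {
    v <- vapply(ok, function(f) {
      x <- f$par[[name]]
      if (is.null(x)) NA_real_ else x
    }, numeric(1))
    if (all(is.na(v))) return(NULL)
    list(mean = mean(v),
         sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
         values = v)
  }
  structure(list(model = ok[[1]]$model, n_total = length(fits),
                 n_converged = length(ok),
                 tau_D = grab(if (ok[[1]]$model == "two_component")
                   "tau_D_slow" else "tau_D"),
                 alpha = grab(if (ok[[1]]$model == "two_component")
                   "alpha_slow" else "alpha"),
                 D = grab("D")),
            class = "cell_measurement")
}

#' Compare diffusion models on one ACF
#'
#' Fits each named model to the same curve and ranks by AIC
#' (`n log(SSR/n) + 2(k+1)`). Per-model fit failures are reported as `NA`
#' rows without aborting the others.
#'
#' @param acf An [acf_curve()].
#' @param models Character vector of registered model names.
#' @param fixed Named list of per-model fixed-parameter lists, e.g.
#'   `list(ou = list(sigma = 0.425))`.
#' @param ... Passed to [fit_acf()].
#' @return data.frame with columns model, ssr, aic, n_free, converged,
#'   ordered by AIC; attribute `"fits"` holds the fit objects.
#' @export
compare_models <- function(acf, models = c("brownian", "anomalous", "ou"),
                           fixed = list(), ...) {
  fits <- lapply(models, function(m) {
    tryCatch(fit_acf(acf, model = m,
                     fixed = if (!is.null(fixed[[m]])) fixed[[m]] else list(),
                     ...),
             error = function(e) NULL)
  })
  names(fits) <- models
  tab <- data.frame(
    model = models,
    ssr = sapply(fits, function(f) if (is.null(f)) NA_real_ else f$ssr),
    aic = sapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic),
    n_free = sapply(fits, function(f) if (is.null(f)) NA_integer_ else f$n_free),
    converged = sapply(fits, function(f) if (is.null(f)) NA else f$converged),
    row.names = NULL)
  tab <- tab[order(tab$aic), ]
  attr(tab, "fits") <- fits
  tab
}

#' Welch's two-sample t-test (heteroscedastic, two-tailed)
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom, the group
#' comparison used throughout the mobility analyses. If both samples have
#' zero variance, equal means give `t = 0, p = 1` by convention.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `dof`, `p` (two-tailed).
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, dof = na + nb - 2, p = 1))
    return(list(t = Inf * sign(mean(a) - mean(b)), dof = na + nb - 2, p = 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, dof = dof, p = 2 * stats::pt(-abs(t), dof))
}

#' SSR profile of the OU fit over a grid of confinement widths
#'
#' Refits the OU model with `sigma` fixed at each grid value (all other
#' defaults as in [fit_acf()]), returning the residual sum of squares
#' profile; used to calibrate `sigma` against hard-wall simulations, where
#' the minimum falls at `sigma ~ d/2`.
#'
#' @param acf An [acf_curve()].
#' @param sigmas Grid of confinement widths (um).
#' @param fixed Additional fixed parameters (e.g. `omega0`, `S`).
#' @param ... Passed to [fit_acf()].
#' @return data.frame with columns sigma, ssr, D, converged.
#' @export
scan_sigma <- function(acf, sigmas, fixed = list(), ...) {
  rows <- lapply(sigmas, function(s) {
    f <- tryCatch(fit_acf(acf, model = "ou",
                          fixed = utils::modifyList(fixed, list(sigma = s)),
                          ...),
                  error = function(e) NULL)
    data.frame(sigma = s,
               ssr = if (is.null(f)) NA_real_ else f$ssr,
               D = if (is.null(f)) NA_real_ else f$par$D,
               converged = if (is.null(f)) NA else f$converged)
  })
  do.call(rbind, rows)
}
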