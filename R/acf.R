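#' Autocorrelation curve container
#'
#' @param lags Strictly increasing lag times (s).
#' @param values Normalized autocorrelation G at each lag (dimensionless).
#' @param sem Optional per-lag dispersion (e.g. SEM across replicate curves).
#' @param min_lag Smallest analyzed lag (s).
#' @return Object of class `acf_curve`.
#' @export
acf_curve <- function(lags, values, sem = NULL, min_lag = min(lags)) {
  stopifnot(length(lags) == length(values), all(diff(lags) > 0),
            all(is.finite(values)), min_lag <= min(lags))
  if (!is.null(sem)) stopifnot(length(sem) == length(values))
  structure(list(lags = as.numeric(lags), values = as.numeric(values),
                 sem = sem, min_lag = min_lag),
            class = "acf_curve")
}

#' Logarithmic lag grid in sample units
#'
#' Log-spaced lag times between `min_lag` and `max_lag`, rounded to integer
#' multiples of `dt_sample` and deduplicated, mirroring hardware-correlator
#' practice.
#'
#' @param dt_sample Sampling interval (s).
#' @param min_lag Smallest lag (s); at least one sample.
#' @param max_lag Largest lag (s).
#' @param points_per_decade Grid density (default 16).
#' @return Integer vector of lags in samples.
#' @export
make_lag_grid <- function(dt_sample, min_lag, max_lag,
                          points_per_decade = 16) {
  stopifnot(min_lag >= dt_sample, max_lag > min_lag)
  n_dec <- log10(max_lag / min_lag)
  lag_s <- 10^seq(log10(min_lag), log10(max_lag),
                  length.out = max(2, ceiling(n_dec * points_per_decade) + 1))
  unique(pmax(1L, as.integer(round(lag_s / dt_sample))))
}

#' Normalized intensity autocorrelation on a log-spaced lag grid
#'
#' `C(dt) = <I(t+dt) I(t)> / (<I(t+dt)> <I(t)>) - 1` with the means taken
#' over the overlapping segment (symmetric normalization), evaluated at
#' log-spaced lags. Symmetric normalization makes the estimator invariant
#' under scaling of the trace and robust to residual slow trends.
#'
#' @param trace An [intensity_trace()].
#' @param lag_grid Optional integer vector of lags in samples; default a
#'   16-per-decade grid from `min_lag` to `duration/10`.
#' @param min_lag Smallest lag (s). Default one sample (simulated traces have
#'   no afterpulsing); experimental photon traces conventionally start at
#'   2e-6 s.
#' @param max_lag Largest lag (s); default a tenth of the trace duration.
#' @param points_per_decade Grid density.
#' @return An [acf_curve()].
#' @export
compute_acf <- function(trace, lag_grid = NULL, min_lag = NULL,
                        max_lag = NULL, points_per_decade = 16) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- trace$values
  if (all(x == 0)) stop("ACF of an all-zero trace is undefined")
  duration <- length(x) * trace$dt_sample
  if (is.null(min_lag)) min_lag <- trace$dt_sample
  if (is.null(max_lag)) max_lag <- duration / 10
  if (is.null(lag_grid)) {
    lag_grid <- make_lag_grid(trace$dt_sample, min_lag, max_lag,
                              points_per_decade)
  }
  lag_grid <- sort(unique(as.integer(lag_grid)))
  if (max(lag_grid) * 2L > length(x)) {
    stop("trace too short: need length >= 2 x max lag")
  }
  vals <- cpp_acf_lags(x, lag_grid)
  acf_curve(lag_grid * trace$dt_sample, vals, min_lag = min_lag)
}

#' Average replicate ACF curves
#'
#' Pointwise mean and SEM across curves sharing the same lag grid.
#'
#' @param curves List of [acf_curve()] objects on identical lag grids.
#' @return An [acf_curve()] with per-lag `sem`.
#' @export
average_acf <- function(curves) {
  stopifnot(length(curves) >= 1)
  lags <- curves[[1]]$lags
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$lags, lags))) stop("lag grids differ")
  }
  vals <- sapply(curves, function(cv) cv$values)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  m <- rowMeans(vals)
  s <- if (length(curves) > 1) {
    apply(vals, 1, stats::sd) / sqrt(length(curves))
  }
  acf_curve(lags, m, sem = s, min_lag = curves[[1]]$min_lag)
}

#' Multiply an ACF by the chromophore-blinking decay
#'
#' Applies the factor `1 + (amplitude/(1 + amplitude)) exp(-dt / tau_H)`
#' (for the default amplitude 0.1 this is `1 + 0.1 exp(-dt/tau_H) / 1.1`),
#' emulating the fast protonation-deprotonation component of GFP-family
#' chromophores. Algebraically identical to the blinking term of the ACF
#' models with dark fraction `F_P = amplitude / (1 + amplitude)` (0.1 gives
#' `F_P = 1/12`) and lifetime `tau_P = tau_H`.
#'
#' @param acf An [acf_curve()].
#' @param amplitude Blinking contrast (default 0.1).
#' @param tau_H Blinking lifetime (s, default 25e-6).
#' @return The modified [acf_curve()].
#' @export
apply_blinking_factor <- function(acf, amplitude = 0.1, tau_H = 25e-6) {
  stopifnot(inherits(acf, "acf_curve"), amplitude >= 0, tau_H > 0)
  fac <- 1 + (amplitude / (1 + amplitude)) * exp(-acf$lags / tau_H)
  acf_curve(acf$lags, acf$values * fac, sem = acf$sem, min_lag = acf$min_lag)
}

#' Photobleaching detrending of an intensity trace
#'
#' Fits a continuous piecewise-linear trend `f(t)` with `n_segments` segments
#' (interior knots chosen by grid search over coarse-bin boundaries,
#' minimizing the residual sum of squares of the binned trace) and applies
#' the variance-preserving square-root correction
#' `I_c(t) = I(t) / sqrt(f(t)/f(0)) + f(0) (1 - sqrt(f(t)/f(0)))`,
#' which restores both the mean and the fluctuation amplitude of a
#' stationary process whose intensity decays multiplicatively.
#'
#' @param trace An [intensity_trace()].
#' @param n_segments Number of linear segments (default 2).
#' @param n_bins Coarse bins used to fit the trend (default 50; must be at
#'   least `2 * n_segments`).
#' @return A detrended [intensity_trace()] with attribute-free values; the
#'   fitted trend (at bin centers) is stored in `meta$trend`.
#' @export
detrend_trace <- function(trace, n_segments = 2, n_bins = 50) {
  stopifnot(inherits(trace, "intensity_trace"),
            n_segments >= 1, n_bins >= 2 * n_segments)
  x <- trace$values
  n <- length(x)
  if (n < 4 * n_bins) stop("trace too short for the requested binning")
  bin <- floor(n / n_bins)
  used <- bin * n_bins
  ybin <- colMeans(matrix(x[seq_len(used)], nrow = bin))
  tbin <- (seq_len(n_bins) - 0.5) * bin * trace$dt_sample
  fitb <- fit_segmented_line(tbin, ybin, n_segments)
  # the trend is piecewise linear: evaluating at knots + ends and
  # interpolating is exact at full resolution
  tt <- seq(0, n - 1) * trace$dt_sample
  nodes <- sort(unique(c(0, fitb$knots, max(tt))))
  f <- stats::approx(nodes, eval_segmented_line(fitb, nodes), xout = tt,
                     rule = 2)$y
  f0 <- eval_segmented_line(fitb, 0)
  if (any(f <= 0) || f0 <= 0) stop("fitted trend is nonpositive; cannot detrend")
  s <- sqrt(f / f0)
  intensity_trace(pmax(x / s + f0 * (1 - s), 0), trace$dt_sample,
                  t_start = trace$t_start,
                  meta = c(trace$meta,
                           list(trend = list(t = tbin,
                                             f = eval_segmented_line(fitb, tbin),
                                             knots = fitb$knots))))
}

# least-squares continuous piecewise-linear fit with n_segments segments;
# interior knots searched over the coarse-grid abscissae
fit_segmented_line <- function(t, y, n_segments) {
  if (n_segments == 1) {
    co <- stats::coef(stats::lm(y ~ t))
    return(list(knots = numeric(0), intercept = co[1], slopes = co[2]))
  }
  if (n_segments > 3) stop("n_segments > 3 not supported")
  # keep at least a fifth of the bins in every segment: slow intrinsic
  # fluctuations near the trace edges otherwise masquerade as a steep trend
  margin <- max(2, ceiling(length(t) / 5))
  idx <- seq(margin, length(t) - margin + 1)
  cand <- if (n_segments == 2) matrix(t[idx], ncol = 1) else
    t(utils::combn(t[idx], 2))
  best <- NULL
  best_ss <- Inf
  for (i in seq_len(nrow(cand))) {
    ks <- sort(cand[i, ])
    X <- cbind(1, t, sapply(ks, function(k) pmax(t - k, 0)))
    fit <- stats::lm.fit(X, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss) {
      best_ss <- ss
      best <- list(knots = ks, intercept = fit$coefficients[1],
                   slopes = fit$coefficients[-1])
    }
  }
  best
}

eval_segmented_line <- function(fit, t) {
  out <- fit$intercept + fit$slopes[1] * t
  if (length(fit$knots) > 0) {
    for (j in seq_along(fit$knots)) {
      out <- out + fit$slopes[j + 1] * pmax(t - fit$knots[j], 0)
    }
  }
  unname(out)
}
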