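# unit bridge: kBT in pN nm, V in um^3, Z0 in um, g in m/s^2 -> kg/m^3 (= g/L)
# kBT [J] / (drho [kg/m^3] * V [m^3] * g [m/s^2]) = Z0 [m]
.kbt_joule <- function(kBT_pN_nm) kBT_pN_nm * 1e-21

#' Barometric decay length from a buoyant density difference
#'
#' Sedimentation-diffusion equilibrium of cells in a density-matched fluid
#' gives an exponential vertical profile `n(z) = n0 exp(-z/Z0)` with
#' `1/Z0 = delta_rho V g / kB T`.
#'
#' @param delta_rho Buoyant density difference (g/L = kg/m^3).
#' @param V Cell volume (um^3).
#' @param g Gravitational acceleration (m/s^2).
#' @param kBT Thermal energy (pN nm; 4.11 at 25 C).
#' @return Decay length Z0 (um); `Inf` when `delta_rho = 0`.
#' @export
decay_length_from_density <- function(delta_rho, V, g = 9.81, kBT = 4.11) {
  stopifnot(V > 0, g > 0, kBT > 0)
  if (delta_rho == 0) return(Inf)
  .kbt_joule(kBT) / (delta_rho * (V * 1e-18) * g) * 1e6
}

#' Buoyant density difference from a fitted decay length
#'
#' Inverts the barometric relation: `delta_rho = kB T / (V g Z0)`, reported
#' in g/L (= kg/m^3). Exact inverse of [decay_length_from_density()];
#' `Z0 = Inf` maps to `delta_rho = 0`.
#'
#' @param Z0 Decay length (um), with optional standard error `Z0_se`.
#' @param V Cell volume (um^3).
#' @param Z0_se Optional SE of `Z0` for delta-method error propagation.
#' @param g,kBT As in [decay_length_from_density()].
#' @return List with `delta_rho` (g/L) and `se` (NA if no `Z0_se`).
#' @export
buoyant_density <- function(Z0, V, Z0_se = NA, g = 9.81, kBT = 4.11) {
  stopifnot(V > 0, g > 0, kBT > 0, Z0 > 0)
  if (is.infinite(Z0)) return(list(delta_rho = 0, se = NA_real_))
  dr <- .kbt_joule(kBT) / ((V * 1e-18) * g * (Z0 * 1e-6))
  list(delta_rho = dr, se = if (is.na(Z0_se)) NA_real_ else dr * Z0_se / Z0)
}

#' Synthetic vertical density profile of sedimenting cells
#'
#' Bins the channel height, computes expected occupancies from the
#' barometric law for the given buoyant density difference and cell volume,
#' and draws multinomial counts. Uses R's RNG.
#'
#' @param delta_rho Buoyant density difference (g/L); 0 gives a uniform
#'   expectation.
#' @param V Cell volume (um^3).
#' @param n_cells Total cells counted.
#' @param n_bins Number of z bins (default 50, i.e. 1 um bins in a 50 um
#'   channel, the imaging z-step).
#' @param channel_height Channel height (um, default 50).
#' @param g,kBT Physical constants, see [decay_length_from_density()].
#' @return List of class `density_profile`: `z` (bin centers, um), `counts`,
#'   `expected`, `channel_height`, `Z0_true`.
#' @export
generate_profile <- function(delta_rho, V, n_cells = 5000, n_bins = 50,
                             channel_height = 50, g = 9.81, kBT = 4.11) {
  stopifnot(n_cells >= 1, n_bins >= 2, channel_height > 0, delta_rho >= 0)
  Z0 <- decay_length_from_density(delta_rho, V, g, kBT)
  z <- (seq_len(n_bins) - 0.5) * channel_height / n_bins
  p <- if (is.infinite(Z0)) rep(1 / n_bins, n_bins) else {
    q <- exp(-z / Z0)
    q / sum(q)
  }
  counts <- as.numeric(stats::rmultinom(1, n_cells, p))
  structure(list(z = z, counts = counts, expected = n_cells * p,
                 channel_height = channel_height, Z0_true = Z0),
            class = "density_profile")
}

#' Fit the exponential decay length of a density profile
#'
#' Fit of `n(z) = n0 exp(-z/Z0)` restricted to an interior height window
#' (default `[0.25, 0.8] x channel_height`, avoiding sample boundaries).
#' The decay is exactly log-linear in `z`, so the default estimator is
#' Poisson regression with a log link (the maximum-likelihood estimator for
#' counted cells, quasi-family so fractional "counts" are accepted and the
#' standard error absorbs over/underdispersion). A plain log-linear
#' least-squares fit is available via `method = "loglinear"` (zero-count
#' bins dropped); note that weighting a nonlinear fit by *observed* counts
#' would correlate weights with noise and bias the rate downward.
#' Near-uniform profiles (fitted rate not distinguishable from zero, or
#' negative) return `Z0 = Inf`.
#'
#' @param profile A `density_profile`, or a list/data.frame with `z`,
#'   `counts` and `channel_height`.
#' @param fit_range Fractional height window (default `c(0.25, 0.8)`).
#' @param method `"poisson"` (log-link regression, default) or
#'   `"loglinear"`.
#' @return List: `Z0` (um), `se`, `n0`, `n_bins_used`, `infinite` flag.
#' @export
fit_decay_length <- function(profile, fit_range = c(0.25, 0.8),
                             method = c("poisson", "loglinear")) {
  method <- match.arg(method)
  h <- profile$channel_height
  stopifnot(!is.null(h), length(fit_range) == 2, fit_range[1] < fit_range[2])
  keep <- profile$z >= fit_range[1] * h & profile$z <= fit_range[2] * h
  z <- profile$z[keep]
  y <- profile$counts[keep]
  if (length(z) < 5) stop("need >= 5 bins inside the fit range")
  if (sum(y > 0) < 3) stop("too few nonzero bins to fit")
  if (method == "loglinear") {
    pos <- y > 0
    fit <- stats::lm(log(y[pos]) ~ z[pos])
  } else {
    fit <- stats::glm(y ~ z, family = stats::quasipoisson(link = "log"))
  }
  k <- -unname(stats::coef(fit)[2])
  k_se <- summary(fit)$coefficients[2, 2]
  n0 <- exp(unname(stats::coef(fit)[1]))
  if (k <= 0 || k < 1e-9) {
    return(list(Z0 = Inf, se = NA_real_, n0 = n0,
                n_bins_used = length(z), infinite = TRUE))
  }
  list(Z0 = 1 / k, se = k_se / k^2, n0 = n0,
       n_bins_used = length(z), infinite = FALSE)
}
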