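#' Covariance of fractional Gaussian noise increments
#'
#' Per-axis increment covariance at integer lag `k` for step `dt` and
#' generalized diffusion coefficient `Gamma` (um^2 / s^alpha):
#' `gamma(k) = (Gamma/2) dt^alpha (|k+1|^alpha + |k-1|^alpha - 2 |k|^alpha)`.
#' At lag 0 this is the per-step variance `Gamma dt^alpha`; for `alpha = 1`
#' it vanishes at all positive lags (white noise).
#'
#' @param k Integer lag(s), `k >= 0`.
#' @param alpha Subdiffusion exponent in (0, 1].
#' @param Gamma Generalized diffusion coefficient (um^2 s^-alpha).
#' @param dt Step duration (s).
#' @return Covariance values (um^2).
#' @export
fgn_covariance <- function(k, alpha, Gamma, dt) {
  (Gamma / 2) * dt^alpha * (abs(k + 1)^alpha + abs(k - 1)^alpha - 2 * abs(k)^alpha)
}

#' Generate fractional Gaussian noise by circulant embedding
#'
#' Davies-Harte method: the increment covariance is embedded in a circulant
#' matrix whose eigenvalues are obtained by one FFT; sample paths are then
#' synthesized by coloring complex white noise with the square-root spectrum.
#' The real and imaginary parts of one synthesis are two independent paths,
#' so paths are produced in pairs at half the FFT cost.
#'
#' For fGn the embedding spectrum is nonnegative; the generator fails loudly
#' if eigenvalues are negative beyond numerical tolerance.
#'
#' @param n_steps Number of increments per path.
#' @param alpha Subdiffusion exponent in (0, 1]; `alpha = 1` gives
#'   uncorrelated Gaussian increments of variance `Gamma * dt`.
#' @param Gamma Generalized diffusion coefficient (um^2 s^-alpha); the
#'   unconfined per-axis MSD of the cumulated path is `Gamma t^alpha`.
#' @param dt Step duration (s).
#' @param n_paths Number of independent paths to return.
#' @return If `n_paths == 1`, a numeric vector of increments (um); otherwise
#'   an `n_steps x n_paths` matrix. Uses R's RNG (respects [set.seed()]).
#' @examples
#' set.seed(1)
#' eta <- generate_fgn(1024, alpha = 0.8, Gamma = 1, dt = 1e-3)
#' var(eta) # ~ Gamma * dt^alpha
#' @export
generate_fgn <- function(n_steps, alpha, Gamma, dt, n_paths = 1) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  stopifnot(n_steps >= 1, Gamma > 0, dt > 0, n_paths >= 1)
  if (alpha == 1) { # analytic collapse to white noise
    out <- matrix(stats::rnorm(n_steps * n_paths, sd = sqrt(Gamma * dt)),
                  n_steps, n_paths)
    return(if (n_paths == 1) out[, 1] else out)
  }
  lam <- fgn_embedding_eigenvalues(n_steps, alpha, Gamma, dt)
  sq <- sqrt(lam / length(lam))
  # synthesis runs in the compiled kernel; its substream is seeded from R's
  # RNG so the whole call respects set.seed()
  seed <- stats::runif(1, 1, 2^31 - 1)
  out <- cpp_fgn_paths(n_steps, sq, n_paths, seed)
  if (n_paths == 1) out[, 1] else out
}

# Eigenvalues of the circulant embedding of the fGn covariance, padded to a
# power of two for FFT speed. Cached on the most recent (n, alpha, Gamma, dt).
fgn_embedding_eigenvalues <- function(n_steps, alpha, Gamma, dt) {
  key <- c(n_steps, alpha, Gamma, dt)
  cache <- .fgn_cache
  if (!is.null(cache$key) && identical(cache$key, key)) return(cache$lam)
  m <- 2^ceiling(log2(2 * n_steps))
  g <- fgn_covariance(0:(m / 2), alpha, Gamma, dt)
  first_row <- c(g, rev(g[2:(m / 2)]))
  lam <- Re(stats::fft(first_row))
  tol <- 1e-10 * max(lam)
  if (any(lam < -tol)) {
    stop("circulant embedding has negative eigenvalues beyond tolerance")
  }
  lam <- pmax(lam, 0)
  .fgn_cache$key <- key
  .fgn_cache$lam <- lam
  lam
}

.fgn_cache <- new.env(parent = emptyenv())

#' Match a generalized diffusion coefficient to a Brownian one
#'
#' Chooses `Gamma` so the per-axis MSD of fractional Brownian motion,
#' `Gamma t^alpha`, equals the Brownian MSD `2 D t` at the matching time
#' `t_match` (default 1 ms, the scale of the confocal transit time).
#'
#' @param D Brownian diffusion coefficient (um^2/s).
#' @param alpha Subdiffusion exponent in (0, 1].
#' @param t_match Time at which the two MSDs agree (s).
#' @return Gamma (um^2 s^-alpha).
#' @export
gamma_for_D <- function(D, alpha, t_match = 1e-3) {
  stopifnot(D > 0, t_match > 0)
  2 * D * t_match^(1 - alpha)
}
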