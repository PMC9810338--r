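#' Blinking (dark-state) multiplier of the FCS models
#'
#' `(1 - F_P + F_P exp(-tau/tau_P)) / (1 - F_P)`: the contribution of a fast
#' reversible dark state (chromophore protonation) with dark fraction `F_P`
#' and lifetime `tau_P`. Equals 1 for all lags when `F_P = 0` and
#' `1/(1 - F_P)` at zero lag.
#'
#' @param tau Lag time(s) (s).
#' @param F_P Dark-state fraction in `[0, 1)`.
#' @param tau_P Dark-state lifetime (s).
#' @return Multiplier, vectorized over `tau`.
#' @export
blinking_term <- function(tau, F_P, tau_P = 25e-6) {
  if (F_P < 0 || F_P >= 1) stop("F_P must be in [0, 1)")
  stopifnot(tau_P > 0)
  (1 - F_P + F_P * exp(-tau / tau_P)) / (1 - F_P)
}

# diffusion factor pair of the 3D anomalous model (without amplitude/blinking)
anomalous_diffusion_factor <- function(tau, tau_D, alpha, S) {
  u <- (tau / tau_D)^alpha
  1 / ((1 + u) * sqrt(1 + u / S^2))
}

#' 3D anomalous-diffusion ACF model
#'
#' `G(tau) = G_inf + (1/N) B(tau) [1 + (tau/tau_D)^alpha]^-1
#'           [1 + (tau/tau_D)^alpha / S^2]^-1/2`
#' with `B` the [blinking_term()]. With `alpha = 1` this is the standard
#' unconfined 3D Brownian FCS model.
#'
#' @param tau Lag time(s) (s).
#' @param N Mean number of particles in the confocal volume.
#' @param tau_D Diffusion (residence) time (s).
#' @param alpha Anomalous diffusion exponent.
#' @param F_P Dark-state fraction.
#' @param tau_P Dark-state lifetime (s).
#' @param S Confocal aspect ratio `z0/omega0`.
#' @param G_inf Long-lag offset.
#' @return G values, vectorized over `tau`.
#' @export
acf_anomalous <- function(tau, N, tau_D, alpha = 1, F_P = 0, tau_P = 25e-6,
                          S = 8, G_inf = 0) {
  if (tau_D <= 0) stop("tau_D must be positive")
  stopifnot(N > 0, S >= 1)
  G_inf + (1 / N) * blinking_term(tau, F_P, tau_P) *
    anomalous_diffusion_factor(tau, tau_D, alpha, S)
}

#' Ornstein-Uhlenbeck confined-diffusion ACF model
#'
#' Brownian motion across the cell width is approximated by an OU process:
#' diffusion with coefficient `D` trapped in a harmonic potential of width
#' `sigma` (standard deviation of the stationary Gaussian), with `sigma ~ d/2`
#' calibrated against hard-wall simulations. The cell's long axis is free.
#' With `tau_D = omega0^2 / (4 D)` and
#' `E(tau) = 1 - exp(-2 D tau / sigma^2)`:
#'
#' `G(tau) = G_inf + (1/N) B(tau)
#'   [1 + (2 sigma^2/omega0^2) E / (1 + omega0^2/(8 sigma^2))]^-1/2  (confined, waist omega0)
#'   [1 + tau/tau_D]^-1/2                                            (free axis)
#'   [1 + (2 sigma^2/(S omega0)^2) E / (1 + (S omega0)^2/(8 sigma^2))]^-1/2 (confined, waist S omega0)`
#'
#' As `sigma -> Inf` each confined factor reduces to its unconfined Brownian
#' counterpart and the model collapses to the standard 3D Brownian ACF.
#'
#' @param tau Lag time(s) (s).
#' @param N Mean occupancy of the confocal volume.
#' @param D Diffusion coefficient (um^2/s).
#' @param sigma Confinement width (um), typically `d/2`.
#' @param omega0 Lateral beam waist (um).
#' @param F_P,tau_P Blinking parameters, see [blinking_term()].
#' @param S Confocal aspect ratio.
#' @param G_inf Long-lag offset.
#' @return G values, vectorized over `tau`.
#' @export
acf_ou <- function(tau, N, D, sigma, omega0 = 0.19, F_P = 0, tau_P = 25e-6,
                   S = 8, G_inf = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(N > 0, D > 0, omega0 > 0, S >= 1)
  tau_D <- omega0^2 / (4 * D)
  E <- -expm1(-2 * D * tau / sigma^2) # 1 - exp(-x), stable for tiny x
  conf <- function(w) 1 / sqrt(1 + (2 * sigma^2 / w^2) * E /
                                 (1 + w^2 / (8 * sigma^2)))
  G_inf + (1 / N) * blinking_term(tau, F_P, tau_P) *
    conf(omega0) * (1 / sqrt(1 + tau / tau_D)) * conf(S * omega0)
}

#' Two-component anomalous-diffusion ACF model
#'
#' Mixture of two anomalous-diffusion species sharing the blinking term and
#' amplitude: `G = G_inf + (1/N) B(tau) [w g(tau; fast) + (1-w) g(tau; slow)]`
#' where `g` is the anomalous diffusion factor pair. Used as a control for a
#' contaminating fraction of fast-diffusing free fluorophore.
#'
#' @param tau Lag time(s) (s).
#' @param N Amplitude occupancy.
#' @param w Weight of the fast component.
#' @param tau_D_fast,alpha_fast Fast-component parameters.
#' @param tau_D_slow,alpha_slow Slow-component parameters.
#' @param F_P,tau_P,S,G_inf As in [acf_anomalous()].
#' @return G values.
#' @export
acf_two_component <- function(tau, N, w, tau_D_fast, alpha_fast,
                              tau_D_slow, alpha_slow,
                              F_P = 0, tau_P = 25e-6, S = 8, G_inf = 0) {
  stopifnot(w >= 0, w <= 1, tau_D_fast > 0, tau_D_slow > 0, N > 0)
  G_inf + (1 / N) * blinking_term(tau, F_P, tau_P) *
    (w * anomalous_diffusion_factor(tau, tau_D_fast, alpha_fast, S) +
       (1 - w) * anomalous_diffusion_factor(tau, tau_D_slow, alpha_slow, S))
}

#' Convert between diffusion time and diffusion coefficient
#'
#' `D = omega0^2 / (4 tau_D)`: lateral transit across the 1/e^2 beam waist.
#' The two functions are exact inverses.
#'
#' @param tau_D Diffusion time (s).
#' @param D Diffusion coefficient (um^2/s).
#' @param omega0 Lateral beam waist (um).
#' @return `tau_to_D`: D in um^2/s; `D_to_tau`: tau_D in s.
#' @examples
#' tau_to_D(20.9e-6, omega0 = sqrt(4 * 414 * 20.9e-6)) # 414
#' @export
tau_to_D <- function(tau_D, omega0) {
  if (any(tau_D <= 0) || any(omega0 <= 0)) stop("inputs must be positive")
  omega0^2 / (4 * tau_D)
}

#' @rdname tau_to_D
#' @export
D_to_tau <- function(D, omega0) {
  if (any(D <= 0) || any(omega0 <= 0)) stop("inputs must be positive")
  omega0^2 / (4 * D)
}
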