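#' Motion model for simulated emitters
#'
#' Either pure Brownian motion with diffusion coefficient `D` (per-axis step
#' sd `sqrt(2 D dt)`, unconfined 3D MSD `6 D t`), or fractional Brownian
#' motion with subdiffusion exponent `alpha` and generalized diffusion
#' coefficient `Gamma` (unconfined per-axis MSD `Gamma t^alpha`, 3D MSD
#' `3 Gamma t^alpha`).
#'
#' @param kind `"brownian"` or `"fbm"`.
#' @param D Diffusion coefficient (um^2/s), Brownian only.
#' @param alpha Subdiffusion exponent in (0, 1], fBm only.
#' @param Gamma Generalized diffusion coefficient (um^2 s^-alpha), fBm only.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(kind = c("brownian", "fbm"), D = NULL,
                         alpha = NULL, Gamma = NULL) {
  kind <- match.arg(kind)
  if (kind == "brownian") {
    if (is.null(D) || !is.null(alpha) || !is.null(Gamma)) {
      stop("brownian motion takes exactly D")
    }
    stopifnot(D >= 0)
  } else {
    if (is.null(alpha) || is.null(Gamma) || !is.null(D)) {
      stop("fbm takes exactly (alpha, Gamma)")
    }
    if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
    stopifnot(Gamma > 0)
  }
  structure(list(kind = kind, D = D, alpha = alpha, Gamma = Gamma),
            class = "motion_model")
}

#' Full description of an in-silico FCS acquisition
#'
#' Defaults emulate a confocal FCS measurement on a cephalexin-elongated
#' E. coli cell: 50 point emitters in a 5 um x 0.85 um capsule, Gaussian
#' detection volume with waists 0.2 um (lateral) and 0.8 um (axial) centered
#' on the cell axis 1 um from one pole.
#'
#' @param n_particles Number of emitters (default 50).
#' @param dt Simulation step (s).
#' @param duration Trace length (s); `duration/dt` must be integral.
#' @param geometry A [cell_geometry()].
#' @param confocal A [confocal_volume()], or `NULL` to place the default
#'   volume 1 um from the left pole on the long axis.
#' @param motion A [motion_model()].
#' @param seed Integer seed controlling all randomness of the acquisition.
#' @param boundary `"redraw"` (Brownian default) or `"reflect"`; fBm always
#'   uses reflective boundaries.
#' @param bleach_rate Optional first-order photobleaching rate constant
#'   (1/s at focal intensity); each emitter goes irreversibly dark with
#'   per-step probability `bleach_rate * I_G(r) * dt`. Default 0 (off).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_particles = 50, dt = 1e-5, duration = 20,
                              geometry = cell_geometry(),
                              confocal = NULL,
                              motion = motion_model("brownian", D = 10),
                              seed = 1, boundary = c("redraw", "reflect"),
                              bleach_rate = 0) {
  boundary <- match.arg(boundary)
  if (is.null(confocal)) {
    confocal <- confocal_volume(0.2, 0.8,
                                center = c(-geometry$L / 2 + 1, 0, 0))
  }
  stopifnot(n_particles >= 1, dt > 0, duration > 0, bleach_rate >= 0)
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-6) {
    stop("duration/dt must be an integer number of steps")
  }
  if (!inside_spherocylinder(confocal$center, geometry)) {
    stop("confocal center lies outside the cell")
  }
  structure(list(n_particles = as.integer(n_particles), dt = dt,
                 duration = duration, n_steps = as.integer(round(n_steps)),
                 geometry = geometry, confocal = confocal, motion = motion,
                 seed = seed, boundary = boundary, bleach_rate = bleach_rate),
            class = "simulation_config")
}

#' Intensity trace container
#'
#' @param values Nonnegative intensity per sample (summed PSF units or
#'   photon counts).
#' @param dt_sample Sampling interval (s).
#' @param t_start Time origin (s).
#' @param meta Named list of provenance (seed, config summary, file source).
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(values, dt_sample, t_start = 0, meta = list()) {
  stopifnot(dt_sample > 0, all(is.finite(values)), all(values >= -1e-12))
  structure(list(values = as.numeric(values), dt_sample = dt_sample,
                 t_start = t_start, meta = meta),
            class = "intensity_trace")
}

#' One confined Brownian step for an ensemble of particles
#'
#' Each coordinate is incremented by an independent Gaussian of sd
#' `sqrt(2 D dt)`. With `boundary = "redraw"` any step that leaves the
#' capsule is redrawn (up to `max_redraw` times; on exhaustion the particle
#' stays put and a counter is incremented); with `"reflect"` the proposed
#' position is folded specularly back across the capsule surface. Uses R's
#' RNG. Pass `geom = NULL` for free (unconfined) diffusion.
#'
#' @param positions n x 3 matrix of current positions (um), all inside.
#' @param D Diffusion coefficient (um^2/s).
#' @param dt Step duration (s).
#' @param geom A [cell_geometry()] or `NULL`.
#' @param boundary `"redraw"` or `"reflect"`.
#' @param max_redraw Retry bound for redraw mode.
#' @return n x 3 matrix of new positions, with attribute `redraw_exhausted`
#'   giving the number of particles left in place this step.
#' @export
step_brownian <- function(positions, D, dt, geom = NULL,
                          boundary = c("redraw", "reflect"),
                          max_redraw = 100) {
  boundary <- match.arg(boundary)
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  s <- sqrt(2 * D * dt)
  if (s == 0) {
    attr(positions, "redraw_exhausted") <- 0L
    return(positions)
  }
  prop <- positions + matrix(stats::rnorm(3 * n, sd = s), n, 3)
  exhausted <- 0L
  if (!is.null(geom)) {
    if (boundary == "redraw") {
      bad <- which(!inside_spherocylinder(prop, geom))
      tries <- 1L
      while (length(bad) > 0 && tries < max_redraw) {
        prop[bad, ] <- positions[bad, , drop = FALSE] +
          matrix(stats::rnorm(3 * length(bad), sd = s), length(bad), 3)
        bad <- bad[!inside_spherocylinder(prop[bad, , drop = FALSE], geom)]
        tries <- tries + 1L
      }
      if (length(bad) > 0) {
        prop[bad, ] <- positions[bad, , drop = FALSE]
        exhausted <- length(bad)
      }
    } else {
      prop <- reflect_positions(prop, geom)
    }
  }
  attr(prop, "redraw_exhausted") <- exhausted
  prop
}

# specular fold of points into the capsule (vectorized R mirror of the C++
# kernel, used by the single-step API)
reflect_positions <- function(p, geom) {
  half_cyl <- (geom$L - geom$d) / 2
  r <- geom$d / 2
  for (it in 1:100) {
    out <- which(!inside_spherocylinder(p, geom))
    if (length(out) == 0) break
    q <- p[out, , drop = FALSE]
    ax <- pmin(pmax(q[, 1], -half_cyl), half_cyl)
    vx <- q[, 1] - ax
    dist <- sqrt(vx^2 + q[, 2]^2 + q[, 3]^2)
    f <- (2 * r - dist) / dist
    p[out, ] <- cbind(ax + vx * f, q[, 2] * f, q[, 3] * f)
  }
  p
}

#' Simulate a fluorescence intensity trace
#'
#' Runs the configured particles through the capsule and records, at every
#' step, the summed Gaussian-PSF intensity of all (still fluorescent)
#' emitters. Brownian motion uses the compiled kernel with deterministic
#' per-particle RNG substreams derived from `config$seed`; fBm paths are
#' synthesized by the Davies-Harte generator and folded reflectively at the
#' capsule wall. Deterministic: identical config and seed give bit-identical
#' traces.
#'
#' @param config A [simulation_config()].
#' @param initial_positions Optional n x 3 matrix of start positions (um);
#'   default: uniform over the capsule (the stationary law, so no burn-in).
#' @return An [intensity_trace()] with `dt_sample = config$dt`.
#' @examples
#' cfg <- simulation_config(n_particles = 5, dt = 1e-4, duration = 0.05,
#'                          motion = motion_model("brownian", D = 10), seed = 7)
#' tr <- simulate_trace(cfg)
#' length(tr$values)
#' @export
simulate_trace <- function(config, initial_positions = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  geom <- config$geometry
  cv <- config$confocal
  if (!is.null(initial_positions)) {
    if (is.null(dim(initial_positions))) {
      initial_positions <- matrix(initial_positions, ncol = 3)
    }
    stopifnot(nrow(initial_positions) == config$n_particles)
    if (!all(inside_spherocylinder(initial_positions, geom))) {
      stop("initial positions must lie inside the cell")
    }
  }
  meta <- list(seed = config$seed, kind = config$motion$kind,
               n_particles = config$n_particles,
               L = geom$L, d = geom$d)
  if (config$motion$kind == "brownian") {
    res <- cpp_bd_trace(config$n_steps, config$dt, config$motion$D,
                        geom$L, geom$d,
                        cv$center[1], cv$center[2], cv$center[3],
                        cv$omega0, cv$z0,
                        config$n_particles, config$seed,
                        if (config$boundary == "redraw") 0L else 1L,
                        config$bleach_rate, 100L,
                        initial_positions)
    meta$redraw_exhausted <- res$redraw_exhausted
    intensity_trace(res$intensity, config$dt, meta = meta)
  } else {
    simulate_trace_fbm(config, initial_positions, meta)
  }
}

# fBm trace: per particle, three independent fGn increment streams cumulated
# under reflective confinement; the circulant square-root spectrum is
# computed once (R fft, cached) and the synthesis runs in the compiled
# kernel with substreams derived from config$seed.
simulate_trace_fbm <- function(config, initial_positions, meta) {
  geom <- config$geometry
  cv <- config$confocal
  n <- config$n_steps
  lam <- fgn_embedding_eigenvalues(n, config$motion$alpha,
                                   config$motion$Gamma, config$dt)
  sq <- sqrt(lam / length(lam))
  intensity <- cpp_fbm_trace(n, sq, geom$L, geom$d,
                             cv$center[1], cv$center[2], cv$center[3],
                             cv$omega0, cv$z0,
                             config$n_particles, config$seed,
                             initial_positions)
  intensity_trace(intensity, config$dt, meta = meta)
}
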