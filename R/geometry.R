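#' Spherocylindrical (capsule) cell geometry
#'
#' Idealized rod-shaped bacterium: a cylinder of diameter `d` and length
#' `L - d` closed at both ends by hemispherical caps of diameter `d`. The
#' long axis is x and the cell is centered at the origin.
#'
#' @param L Total cell length (um), pole to pole.
#' @param d Cell diameter (um). Must satisfy `L >= d > 0`.
#' @return An object of class `cell_geometry` with fields `L`, `d`.
#' @examples
#' geom <- cell_geometry(L = 5, d = 0.85)
#' spherocylinder_volume(geom$L, geom$d)
#' @export
cell_geometry <- function(L = 5, d = 0.85) {
  stopifnot(is.numeric(L), is.numeric(d), length(L) == 1, length(d) == 1)
  if (!(d > 0 && L >= d)) stop("cell geometry requires L >= d > 0")
  structure(list(L = L, d = d), class = "cell_geometry")
}

#' Gaussian confocal detection volume
#'
#' 3D Gaussian intensity profile with lateral 1/e^2 waist `omega0` and axial
#' 1/e^2 waist `z0`, centered at `center` (um). The aspect ratio `S = z0 /
#' omega0` is stored for convenience.
#'
#' @param omega0 Lateral beam waist (um).
#' @param z0 Axial beam waist (um), `z0 >= omega0`.
#' @param center Numeric length-3 position of the focus (um).
#' @return An object of class `confocal_volume`.
#' @export
confocal_volume <- function(omega0 = 0.2, z0 = 0.8, center = c(0, 0, 0)) {
  stopifnot(length(center) == 3, omega0 > 0, z0 >= omega0)
  structure(list(omega0 = omega0, z0 = z0, center = as.numeric(center),
                 S = z0 / omega0),
            class = "confocal_volume")
}

#' Is a point inside the spherocylinder?
#'
#' Boundary points count as inside. Vectorized over rows of `p`.
#'
#' @param p Numeric length-3 point or n x 3 matrix of points (um).
#' @param geom A [cell_geometry()].
#' @return Logical vector.
#' @examples
#' inside_spherocylinder(c(0, 0, 0), cell_geometry(5, 0.8))
#' @export
inside_spherocylinder <- function(p, geom) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3)
  half_cyl <- (geom$L - geom$d) / 2
  r2 <- (geom$d / 2)^2
  ax <- abs(p[, 1])
  ex <- pmax(ax - half_cyl, 0)
  ex^2 + p[, 2]^2 + p[, 3]^2 <= r2
}

#' Volume of a spherocylinder
#'
#' `V = pi d^3 / 6 + (L - d) pi d^2 / 4`: a sphere of diameter `d` plus the
#' cylindrical midsection.
#'
#' @param L Total length (um).
#' @param d Diameter (um), `L >= d > 0`.
#' @return Volume in um^3.
#' @export
spherocylinder_volume <- function(L, d) {
  if (any(d <= 0) || any(L < d)) stop("spherocylinder requires L >= d > 0")
  pi * d^3 / 6 + (L - d) * pi * d^2 / 4
}

#' Draw uniform positions inside the spherocylinder
#'
#' Rejection sampling from the bounding box. Uniform is the stationary law of
#' confined Brownian motion, so traces need no burn-in.
#'
#' @param n Number of points.
#' @param geom A [cell_geometry()].
#' @return n x 3 matrix of positions (um).
#' @export
sample_uniform_positions <- function(n, geom) {
  out <- matrix(NA_real_, n, 3)
  need <- n
  r <- geom$d / 2
  while (need > 0) {
    m <- max(16L, ceiling(need * 2.5))
    cand <- cbind(stats::runif(m, -geom$L / 2, geom$L / 2),
                  stats::runif(m, -r, r),
                  stats::runif(m, -r, r))
    ok <- cand[inside_spherocylinder(cand, geom), , drop = FALSE]
    k <- min(nrow(ok), need)
    if (k > 0) out[(n - need + 1):(n - need + k), ] <- ok[seq_len(k), ]
    need <- need - k
  }
  out
}

#' Gaussian confocal excitation intensity at a point
#'
#' `exp(-2 [ (dx^2 + dy^2) / omega0^2 + dz^2 / z0^2 ])` relative to the
#' confocal center; equals 1 at the focus.
#'
#' @param p Length-3 point or n x 3 matrix (um).
#' @param confocal A [confocal_volume()].
#' @return Intensity in `[0, 1]`.
#' @export
psf_intensity <- function(p, confocal) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  dx <- p[, 1] - confocal$center[1]
  dy <- p[, 2] - confocal$center[2]
  dz <- p[, 3] - confocal$center[3]
  exp(-2 * ((dx^2 + dy^2) / confocal$omega0^2 + dz^2 / confocal$z0^2))
}
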