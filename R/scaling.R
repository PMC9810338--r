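#' Load the per-construct measurement table
#'
#' Reads the packaged CSV of sfGFP fusion constructs (molecular mass of the
#' fusion, FCS diffusion time and anomalous exponent, FCS and FRAP diffusion
#' coefficients with SEMs and cell counts), or a user file in the same
#' format. Empty cells are `NA`: only a subset of constructs — the
#' apparently freely diffusing ones — carries an FCS diffusion coefficient.
#'
#' @param path CSV path; default the packaged construct table.
#' @return data.frame with columns `name, mm_kda, n_cells_fcs, tau_d_us,
#'   tau_d_sem_us, alpha, alpha_sem, d_fcs_um2_s, d_fcs_sem_um2_s,
#'   n_cells_frap, d_frap_um2_s, d_frap_sem_um2_s`.
#' @export
read_construct_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "construct_table.csv",
                        package = "confinedfcs", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mm_kda", "tau_d_us", "tau_d_sem_us", "alpha",
            "alpha_sem", "d_fcs_um2_s", "d_fcs_sem_um2_s")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("construct table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(tab$mm_kda <= 0, na.rm = TRUE)) stop("molecular masses must be positive")
  tab
}

#' Inverse power-law fit of diffusion coefficient vs molecular mass
#'
#' Nonlinear least squares of `D = A * MM^(-beta)` across constructs,
#' optionally weighted by `1/sem^2` (the default when SEMs are supplied,
#' matching fits to per-construct means with error bars).
#'
#' @param mm Molecular masses (kDa).
#' @param d_value Diffusion coefficients (um^2/s) or mobilities `1/tau_D`.
#' @param sem Optional per-construct SEMs (same units as `d_value`).
#' @param weighted Use `1/sem^2` weights (requires `sem`).
#' @return Object of class `power_law_fit`: `A`, `beta`, standard errors,
#'   covariance, and a `predict(mm)` closure.
#' @examples
#' fit <- fit_power_law(c(27, 50, 100), 100 * c(27, 50, 100)^-0.5)
#' fit$beta
#' @export
fit_power_law <- function(mm, d_value, sem = NULL, weighted = !is.null(sem)) {
  stopifnot(length(mm) == length(d_value), length(mm) >= 3,
            all(mm > 0), all(d_value > 0))
  if (length(unique(mm)) < 2) stop("degenerate design: all masses equal")
  if (weighted && is.null(sem)) stop("weighted fit requires sem")
  w <- if (weighted) 1 / sem^2 else rep(1, length(mm))
  # log-log regression provides starting values for the nonlinear fit
  lm0 <- stats::lm(log(d_value) ~ log(mm), weights = w)
  start <- list(A = exp(unname(stats::coef(lm0)[1])),
                beta = -unname(stats::coef(lm0)[2]))
  fit <- minpack.lm::nlsLM(d_value ~ A * mm^(-beta), start = start,
                           weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  A <- co["A", "Estimate"]
  beta <- co["beta", "Estimate"]
  structure(list(A = A, beta = beta,
                 A_se = co["A", "Std. Error"],
                 beta_se = co["beta", "Std. Error"],
                 cov = stats::vcov(fit), weighted = weighted,
                 n = length(mm),
                 predict = function(mm_new) A * mm_new^(-beta)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law D = A * MM^(-beta): beta = %.3f +- %.3f, A = %.1f (%s, n = %d)\n",
              x$beta, x$beta_se, x$A, if (x$weighted) "weighted" else "unweighted",
              x$n))
  invisible(x)
}

#' Stokes-Einstein reference curve
#'
#' `D(MM) = D_ref * (MM / MM_ref)^(-beta)` anchored at a reference construct,
#' with the radius-mass exponent `beta = 0.4` typical of imperfectly compact
#' globular proteins (`R ~ MM^beta`, empirically 0.35-0.43).
#'
#' @param mm_grid Molecular masses (kDa) to evaluate.
#' @param mm_ref,d_ref Anchor mass (kDa) and diffusion coefficient (um^2/s).
#' @param beta Radius-mass exponent (default 0.4).
#' @return Diffusion coefficients on `mm_grid`.
#' @export
stokes_einstein_curve <- function(mm_grid, mm_ref = 26.9, d_ref = 14.7,
                                  beta = 0.4) {
  stopifnot(mm_ref > 0, d_ref > 0)
  d_ref * (mm_grid / mm_ref)^(-beta)
}

#' Diffusion coefficient of a linked two-bead (dumbbell) fusion protein
#'
#' Hydrodynamic model of a fluorescent-protein fusion as two tethered beads:
#' the tag (radius `a1`) and the target protein (radius `a2`), with radii
#' scaling as `R ~ MM^beta_R` from the tag anchor. The translational
#' diffusion coefficient, at Kirkwood/Oseen level for a rigid pair with
#' center separation `r = a1 + a2 + linker`,
#'
#' `D = D1 * a1/(a1 + a2) * (1 + 3 a1 a2 / (2 (a1 + a2) r))`
#'
#' where `D1` is the single-sphere value of the tag alone. The coupling term
#' reflects that the flow field each bead drags along assists the other, so
#' the pair diffuses faster than a no-interaction pair (`D1 a1/(a1+a2)`) but
#' slower than either isolated bead. Limits: `mm_partner -> 0` recovers the
#' single-sphere tag value; `D` decreases monotonically in either mass.
#'
#' @param mm_partner Target-protein mass (kDa); vectorized.
#' @param mm_gfp Tag mass (kDa, default 26.9 for sfGFP).
#' @param d_gfp Single-sphere diffusion coefficient of the tag in the medium
#'   of interest (um^2/s; default 14.7, cytoplasmic sfGFP).
#' @param beta_R Radius-mass exponent (default 0.4).
#' @param linker Center-gap added by the flexible linker, in units of the
#'   tag radius (default 0: touching beads).
#' @return Effective diffusion coefficient(s) (um^2/s).
#' @export
dumbbell_diffusion <- function(mm_partner, mm_gfp = 26.9, d_gfp = 14.7,
                               beta_R = 0.4, linker = 0) {
  stopifnot(all(mm_partner >= 0), mm_gfp > 0, d_gfp > 0, linker >= 0)
  a1 <- 1
  a2 <- (mm_partner / mm_gfp)^beta_R
  r <- a1 + a2 + linker
  d_gfp * (a1 / (a1 + a2)) * (1 + 1.5 * a1 * a2 / ((a1 + a2) * r))
}
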