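#' Simulate, correlate and fit one FCS measurement (one "cell")
#'
#' Emulates the experimental per-cell protocol: `n_acquisitions` sequential
#' intensity traces at the same spot (acquisition seeds derived from
#' `config$seed`), each optionally detrended, correlated on a log lag grid,
#' multiplied by the blinking decay, and fitted independently; the fitted
#' mobility parameters are then averaged over the converged acquisitions.
#'
#' @param config A [simulation_config()]; its `seed` identifies the cell.
#' @param n_acquisitions Traces per cell (default 6).
#' @param model Fit model (`"anomalous"`, `"ou"` or `"brownian"`).
#' @param fixed Fixed parameters passed to [fit_acf()].
#' @param detrend Apply [detrend_trace()] before correlating.
#' @param blink Multiply ACFs by the blinking factor (default TRUE).
#' @param min_lag,max_lag,points_per_decade Lag grid, see [compute_acf()].
#' @param keep Which intermediates to keep: any of `"traces"`, `"acfs"`.
#' @return List of class `cell_result`: `measurement` (a
#'   [aggregate_cell()] result), `fits`, and any kept intermediates.
#' @export
simulate_cell <- function(config, n_acquisitions = 6,
                          model = "anomalous", fixed = list(),
                          detrend = FALSE, blink = TRUE,
                          min_lag = NULL, max_lag = NULL,
                          points_per_decade = 16, keep = character(0)) {
  stopifnot(inherits(config, "simulation_config"), n_acquisitions >= 1)
  acq_cfgs <- lapply(seq_len(n_acquisitions), function(a) {
    cfg <- config
    cfg$seed <- config$seed * 1000 + a
    cfg
  })
  traces <- lapply(acq_cfgs, simulate_trace)
  if (detrend) traces <- lapply(traces, detrend_trace)
  acfs <- lapply(traces, compute_acf, min_lag = min_lag, max_lag = max_lag,
                 points_per_decade = points_per_decade)
  if (blink) acfs <- lapply(acfs, apply_blinking_factor)
  fits <- lapply(acfs, function(a) {
    tryCatch(fit_acf(a, model = model, fixed = fixed),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all acquisition fits failed")
  out <- list(measurement = aggregate_cell(fits), fits = fits,
              seed = config$seed)
  if ("traces" %in% keep) out$traces <- traces
  if ("acfs" %in% keep) out$acfs <- acfs
  structure(out, class = "cell_result")
}

#' Run the full per-cell workflow over several simulated cells
#'
#' Chains simulate -> (detrend) -> correlate -> blink -> fit -> aggregate for
#' `n_cells` cells with derived seeds, and returns a tidy per-cell summary.
#' Per-cell failures are recorded as `NA` rows rather than aborting the run.
#'
#' @param config Base [simulation_config()]; cell `i` uses seed
#'   `config$seed + i - 1`.
#' @param n_cells Number of independent cells.
#' @param ... Passed to [simulate_cell()].
#' @return data.frame with one row per cell: seed, n_converged, mean/SEM of
#'   `tau_D` (s) and `alpha` (anomalous) or `D` (um^2/s, OU).
#' @export
run_pipeline <- function(config, n_cells = 1, ...) {
  rows <- lapply(seq_len(n_cells), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1
    res <- tryCatch(simulate_cell(cfg, ...), error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(seed = cfg$seed, n_converged = 0L,
                        tau_d_s = NA_real_, tau_d_sem_s = NA_real_,
                        alpha = NA_real_, alpha_sem = NA_real_,
                        d_um2_s = NA_real_, d_sem_um2_s = NA_real_))
    }
    m <- res$measurement
    pick <- function(comp, field) {
      if (is.null(comp)) NA_real_ else comp[[field]]
    }
    data.frame(seed = cfg$seed, n_converged = m$n_converged,
               tau_d_s = pick(m$tau_D, "mean"),
               tau_d_sem_s = pick(m$tau_D, "sem"),
               alpha = pick(m$alpha, "mean"),
               alpha_sem = pick(m$alpha, "sem"),
               d_um2_s = pick(m$D, "mean"),
               d_sem_um2_s = pick(m$D, "sem"))
  })
  do.call(rbind, rows)
}

#' Scan fitted mobility parameters over a grid of cell diameters
#'
#' For each diameter, simulates one cell (six acquisitions by default),
#' fits each acquisition's blinked ACF, and reports the per-diameter mean
#' and SEM of the fitted anomalous exponent (and diffusion time), the
#' confinement-artifact readout: purely Brownian particles confined at
#' bacterial cell widths yield apparent `alpha < 1`.
#'
#' @param diameters Cell diameters to scan (um).
#' @param config Base [simulation_config()]; geometry diameter is replaced
#'   per scan point, seeds derived per diameter.
#' @param model,fixed,n_acquisitions,... Passed to [simulate_cell()].
#' @return data.frame with columns `d_um`, `alpha`, `alpha_sem`, `tau_d_s`,
#'   `tau_d_sem_s`, `d_um2_s`, `d_sem_um2_s`, `n_converged`.
#' @export
scan_diameter <- function(diameters, config, model = "anomalous",
                          fixed = list(), n_acquisitions = 6, ...) {
  rows <- lapply(seq_along(diameters), function(j) {
    cfg <- config
    cfg$geometry <- cell_geometry(config$geometry$L, diameters[j])
    cfg$seed <- config$seed + (j - 1)
    res <- simulate_cell(cfg, n_acquisitions = n_acquisitions, model = model,
                         fixed = fixed, ...)
    m <- res$measurement
    pick <- function(comp, field) if (is.null(comp)) NA_real_ else comp[[field]]
    data.frame(d_um = diameters[j],
               alpha = pick(m$alpha, "mean"), alpha_sem = pick(m$alpha, "sem"),
               tau_d_s = pick(m$tau_D, "mean"),
               tau_d_sem_s = pick(m$tau_D, "sem"),
               d_um2_s = pick(m$D, "mean"), d_sem_um2_s = pick(m$D, "sem"),
               n_converged = m$n_converged)
  })
  do.call(rbind, rows)
}
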