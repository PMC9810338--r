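#' Write / read an intensity trace
#'
#' Plain-text CSV with `#`-prefixed header lines carrying `dt_sample`,
#' `t_start` and provenance metadata, followed by `time_s,intensity`
#' columns. The round trip `write_trace()` then [read_trace()] preserves all
#' numeric fields at full precision.
#'
#' @param trace An [intensity_trace()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "intensity_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_sample=%.17g", trace$dt_sample), con)
  writeLines(sprintf("# t_start=%.17g", trace$t_start), con)
  for (k in names(trace$meta)) {
    v <- trace$meta[[k]]
    if (is.numeric(v) && length(v) == 1) {
      writeLines(sprintf("# meta.%s=%.17g", k, v), con)
    } else if (is.character(v) && length(v) == 1) {
      writeLines(sprintf("# meta.%s=%s", k, v), con)
    }
  }
  writeLines("time_s,intensity", con)
  tt <- trace$t_start + (seq_along(trace$values) - 1) * trace$dt_sample
  writeLines(sprintf("%.17g,%.17g", tt, trace$values), con)
  invisible(path)
}

# parse "# key=value" headers; returns a named character vector
read_hash_header <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  out <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || !startsWith(ln, "#")) break
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      out[substr(kv, 1, eq - 1)] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  out
}

#' @rdname write_trace
#' @param ... unused.
#' @export
read_trace <- function(path, ...) {
  hdr <- read_hash_header(path)
  if (!"dt_sample" %in% names(hdr)) {
    stop("malformed trace file (no dt_sample header): ", path)
  }
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "intensity") %in% names(tab))) {
    stop("trace file must have time_s,intensity columns: ", path)
  }
  meta_keys <- grep("^meta\\.", names(hdr), value = TRUE)
  meta <- lapply(hdr[meta_keys], function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (is.na(nv)) v else nv
  })
  names(meta) <- sub("^meta\\.", "", meta_keys)
  intensity_trace(tab$intensity, as.numeric(hdr["dt_sample"]),
                  t_start = as.numeric(hdr["t_start"]), meta = meta)
}

#' Write / read an ACF curve
#'
#' CSV with a `# min_lag=` header and columns `lag_s,G[,sem]`; the `sem`
#' column is optional on read.
#'
#' @param acf An [acf_curve()].
#' @param path File path.
#' @return `path` invisibly (write); an [acf_curve()] (read).
#' @export
write_acf <- function(acf, path) {
  stopifnot(inherits(acf, "acf_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# min_lag=%.17g", acf$min_lag), con)
  if (is.null(acf$sem)) {
    writeLines("lag_s,G", con)
    writeLines(sprintf("%.17g,%.17g", acf$lags, acf$values), con)
  } else {
    writeLines("lag_s,G,sem", con)
    writeLines(sprintf("%.17g,%.17g,%.17g", acf$lags, acf$values, acf$sem), con)
  }
  invisible(path)
}

#' @rdname write_acf
#' @export
read_acf <- function(path) {
  hdr <- read_hash_header(path)
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("lag_s", "G") %in% names(tab))) {
    stop("ACF file must have lag_s,G columns: ", path)
  }
  acf_curve(tab$lag_s, tab$G,
            sem = if ("sem" %in% names(tab)) tab$sem,
            min_lag = if ("min_lag" %in% names(hdr))
              as.numeric(hdr["min_lag"]) else min(tab$lag_s))
}
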