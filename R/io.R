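# Waveform file formats: a sampled CSV (fixed dwell) and an exact
# breakpoint JSON. Both store the EFFECTIVE waveform in ms and mT/m.

# evaluate a piecewise-linear waveform at arbitrary times; at a jump
# (duplicated breakpoint) the post-jump value is taken
.eval_waveform <- function(w, times) {
  t <- w$breakpoints; g <- w$values; n <- length(t)
  idx <- findInterval(times, t, rightmost.closed = TRUE)
  out <- numeric(length(times))
  for (j in seq_along(times)) {
    i <- idx[j]
    if (i < 1L) { out[j] <- 0; next }
    if (i >= n) { out[j] <- g[n]; next }
    h <- t[i + 1L] - t[i]
    out[j] <- if (h > 0) g[i] + (g[i + 1L] - g[i]) * (times[j] - t[i]) / h
              else g[i + 1L]
  }
  out
}

# integral of G(t)^2 over [from, to] on a piecewise-linear waveform
.gsq_integral <- function(w, from, to) {
  t <- w$breakpoints; g <- w$values
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    lo <- max(t[i], from); hi <- min(t[i + 1L], to)
    if (hi <= lo) next
    h <- t[i + 1L] - t[i]
    glo <- g[i] + (g[i + 1L] - g[i]) * (lo - t[i]) / h
    ghi <- g[i] + (g[i + 1L] - g[i]) * (hi - t[i]) / h
    total <- total + (hi - lo) * (glo^2 + glo * ghi + ghi^2) / 3
  }
  total
}

#' Write a waveform as sampled CSV
#'
#' Header line `# time_ms,gradient_mT_per_m`, an optional metadata comment
#' `# refocus_ms=<x>`, then comma-separated samples at a fixed dwell.
#'
#' @param w An `effective_waveform`.
#' @param path Output file path.
#' @param dwell_us Sampling dwell in microseconds.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path, dwell_us = 10) {
  stopifnot(inherits(w, "effective_waveform"), dwell_us > 0)
  times <- seq(0, max(w$breakpoints), by = dwell_us * 1e-6)
  vals <- .eval_waveform(w, times)
  lines <- c("# time_ms,gradient_mT_per_m")
  if (is.finite(w$refocus))
    lines <- c(lines, sprintf("# refocus_ms=%.10g", .s_to_ms(w$refocus)))
  lines <- c(lines, sprintf("%.10g,%.10g", .s_to_ms(times), .Tmm_to_mTm(vals)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sampled waveform CSV
#'
#' @param path File written by [write_waveform_csv()] (or compatible).
#' @return An `effective_waveform` whose breakpoints are the sample times.
#' @export
read_waveform_csv <- function(path) {
  lines <- readLines(path)
  refocus <- NA_real_
  data_idx <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  meta <- grep("^#\\s*refocus_ms=", lines, value = TRUE)
  if (length(meta))
    refocus <- .ms_to_s(as.numeric(sub("^#\\s*refocus_ms=", "", meta[1L])))
  if (!length(data_idx)) stop("no samples found in ", path)
  parts <- strsplit(lines[data_idx], ",")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop(sprintf("parse error in %s at line %d: expected 'time,gradient'",
                 path, data_idx[bad[1L]]))
  t <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  g <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(t) || anyNA(g))
    stop(sprintf("parse error in %s at line %d: non-numeric value",
                 path, data_idx[which(is.na(t) | is.na(g))[1L]]))
  # tolerate truncated files that do not return to zero
  if (g[1L] != 0) { t <- c(t[1L], t); g <- c(0, g) }
  n <- length(g)
  if (g[n] != 0) { t <- c(t, t[n]); g <- c(g, 0) }
  new_effective_waveform(.ms_to_s(t), .mTm_to_Tmm(g), refocus = refocus)
}

#' Write a waveform as exact breakpoint JSON
#'
#' Format: `{"breakpoints_ms": [...], "values_mT_per_m": [...],
#' "refocus_ms": x}`. This representation is exact; re-reading reproduces
#' moments to machine precision.
#'
#' @inheritParams write_waveform_csv
#' @return `path`, invisibly.
#' @export
write_waveform_json <- function(w, path) {
  stopifnot(inherits(w, "effective_waveform"))
  jsonlite::write_json(
    list(breakpoints_ms = .s_to_ms(w$breakpoints),
         values_mT_per_m = .Tmm_to_mTm(w$values),
         refocus_ms = if (is.finite(w$refocus)) .s_to_ms(w$refocus) else NULL),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a breakpoint JSON waveform
#'
#' @param path File written by [write_waveform_json()] (or compatible).
#' @return An `effective_waveform`.
#' @export
read_waveform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$breakpoints_ms) || is.null(x$values_mT_per_m))
    stop("parse error in ", path, ": breakpoints_ms / values_mT_per_m missing")
  refocus <- if (!is.null(x$refocus_ms)) .ms_to_s(x$refocus_ms) else NA_real_
  new_effective_waveform(.ms_to_s(x$breakpoints_ms),
                         .mTm_to_Tmm(x$values_mT_per_m), refocus = refocus)
}

#' Read a waveform file (CSV or JSON by extension)
#'
#' @param path Waveform file.
#' @return An `effective_waveform`.
#' @export
read_waveform <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_waveform_json(path)
  else read_waveform_csv(path)
}
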