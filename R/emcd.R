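# Empirical Mean Curve Decomposition: alternating-extrema detection, spline
# envelopes, the mean curve, empirical-waveform statistics, the iterated
# decomposition into oscillatory modes plus a leftover trend, and the inverse
# (summation) reconstruction.

#' Find strict local extrema of a signal
#'
#' Plateaus take the plateau midpoint; endpoints are excluded. Maxima and
#' minima alternate when merged by index.
#'
#' @param signal numeric vector.
#' @return object of class `extrema_series`: list with data frames `maxima`
#'   and `minima`, each with columns `index` and `value`.
#' @export
find_extrema <- function(signal) {
  n <- length(signal)
  empty <- data.frame(index = integer(0), value = numeric(0))
  if (n < 3) return(structure(list(maxima = empty, minima = empty),
                              class = "extrema_series"))
  r <- rle(signal)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  max_idx <- integer(0); min_idx <- integer(0)
  if (k >= 3) {
    v <- r$values
    mid <- (starts + ends) %/% 2L           # plateau midpoint convention
    i <- 2:(k - 1L)
    is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
    is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
    max_idx <- mid[i][is_max]
    min_idx <- mid[i][is_min]
  }
  structure(list(
    maxima = data.frame(index = max_idx, value = signal[max_idx]),
    minima = data.frame(index = min_idx, value = signal[min_idx])),
    class = "extrema_series")
}

#' Spline envelope through a set of extrema
#'
#' A cubic interpolating spline through the requested extrema, evaluated at
#' `t = 1..len`; beyond the first/last extremum the envelope is extended by
#' the nearest extremum value (constant extension). With exactly two points
#' the interpolant degenerates to the line through them.
#'
#' @param extrema an `extrema_series` from [find_extrema()].
#' @param len output length `T`.
#' @param which `"superior"` (through maxima) or `"inferior"` (through minima).
#' @return numeric vector of length `len`.
#' @export
envelope <- function(extrema, len, which = c("superior", "inferior")) {
  which <- match.arg(which)
  pts <- if (which == "superior") extrema$maxima else extrema$minima
  if (nrow(pts) < 2)
    stop(errorCondition(sprintf("need >= 2 %s extrema (got %d)", which, nrow(pts)),
                        class = c("ocuclean_needs_extrema", "error")))
  t_eval <- pmin(pmax(seq_len(len), pts$index[1]), pts$index[nrow(pts)])
  if (nrow(pts) == 2) {
    slope <- (pts$value[2] - pts$value[1]) / (pts$index[2] - pts$index[1])
    return(pts$value[1] + slope * (t_eval - pts$index[1]))
  }
  f <- stats::splinefun(pts$index, pts$value, method = "natural")
  f(t_eval)
}

#' Mean curve of a signal
#'
#' The average of the superior (through maxima) and inferior (through minima)
#' spline envelopes; the global trend of the signal.
#'
#' @param signal numeric vector with at least two maxima and two minima.
#' @return numeric vector of the same length.
#' @export
mean_curve <- function(signal) {
  ex <- find_extrema(signal)
  (envelope(ex, length(signal), "superior") +
     envelope(ex, length(signal), "inferior")) / 2
}

#' Empirical-waveform statistics
#'
#' The mode count `md` is the average of the numbers of maxima and minima
#' (possibly a half-integer); the empirical period is `T / md` samples and
#' the empirical frequency `md / T` cycles per sample (so `EP * EF == 1`
#' whenever `md > 0`). A signal without extrema has `md = 0` and
#' `EP`/`EF` reported as `NaN`.
#'
#' @param signal numeric vector.
#' @return object of class `ewf_stats` with `mode_count`, `empirical_period`,
#'   `empirical_frequency`.
#' @export
ewf_stats <- function(signal) {
  ex <- find_extrema(signal)
  md <- (nrow(ex$maxima) + nrow(ex$minima)) / 2
  T <- length(signal)
  structure(list(mode_count = md,
                 empirical_period = if (md > 0) T / md else NaN,
                 empirical_frequency = if (md > 0) md / T else NaN),
            class = "ewf_stats")
}

#' Empirical Mean Curve Decomposition
#'
#' Iteratively extracts oscillatory modes: at each level the mode is the
#' current signal minus its mean curve, and the mean curve becomes the current
#' signal. Iteration stops at `max_levels` or as soon as the current signal
#' has fewer than two maxima or two minima; the final current signal is the
#' leftover trend. By construction the modes and leftover sum exactly to the
#' input (telescoping), so the inverse is plain summation.
#'
#' @param signal numeric vector of length >= 8.
#' @param max_levels maximum number of modes (default 5).
#' @return object of class `emcd_result`: list with `modes` (list of numeric
#'   vectors), `leftover`, `n_levels`.
#' @export
emcd_decompose <- function(signal, max_levels = 5) {
  if (length(signal) < 8)
    stop(errorCondition("signal too short for EMCD (need length >= 8)",
                        class = c("ocuclean_decomposition_error", "error")))
  max_levels <- check_count(max_levels, "max_levels")
  cur <- signal
  modes <- list()
  for (k in seq_len(max_levels)) {
    ex <- find_extrema(cur)
    if (nrow(ex$maxima) < 2 || nrow(ex$minima) < 2) break
    m <- (envelope(ex, length(cur), "superior") +
            envelope(ex, length(cur), "inferior")) / 2
    modes[[k]] <- cur - m
    cur <- m
  }
  structure(list(modes = modes, leftover = cur, n_levels = length(modes)),
            class = "emcd_result")
}

#' @export
print.emcd_result <- function(x, ...) {
  cat(sprintf("<emcd_result> %d modes + leftover, length %d\n",
              x$n_levels, length(x$leftover)))
  invisible(x)
}

#' Inverse EMCD: reconstruct a signal from (possibly restored) modes
#'
#' @param restored_modes list of numeric mode vectors (may be empty).
#' @param leftover the leftover trend vector.
#' @return numeric vector: elementwise sum of all modes and the leftover.
#' @export
inverse_emcd <- function(restored_modes, leftover) {
  out <- leftover
  for (m in restored_modes) {
    if (length(m) != length(leftover)) stop_arg("mode/leftover length mismatch")
    out <- out + m
  }
  out
}
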