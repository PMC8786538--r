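# Detection-phase decomposition: a five-level four-band wavelet filter
# cascade (two cascaded two-channel splits per level, recursing on the
# low-low band) followed by Pisarenko harmonic analysis of each subband.

# Orthogonal decomposition filter pairs (analysis low/high). These are the
# standard Daubechies quadrature-mirror coefficients; db4 (8 taps, 4
# vanishing moments) is the default, being a common choice for EEG.
.wavelet_filters <- list(
  db4 = list(
    lo = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
           -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
           0.71484657055291567, 0.23037781330889651),
    hi = c(-0.23037781330889651, 0.71484657055291567, -0.63088076792985892,
           -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
           -0.032883011666885197, -0.010597401785069032)),
  db2 = list(
    lo = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
           0.48296291314453416),
    hi = c(-0.48296291314453416, 0.83651630373780794, -0.22414386804201339,
           -0.12940952255126037)),
  haar = list(
    lo = c(0.70710678118654757, 0.70710678118654757),
    hi = c(-0.70710678118654757, 0.70710678118654757))
)

wavelet_filter <- function(wavelet_name) {
  f <- .wavelet_filters[[wavelet_name]]
  if (is.null(f)) stop_arg(sprintf("unknown wavelet '%s' (available: %s)",
                                   wavelet_name, paste(names(.wavelet_filters), collapse = ", ")))
  f
}

# Full (zero-extension) convolution; y[j] = sum_m x[m] f[j - m].
conv_full <- function(x, f) {
  n <- length(x); m <- length(f)
  out <- numeric(n + m - 1)
  for (j in seq_len(m)) out[j:(j + n - 1)] <- out[j:(j + n - 1)] + f[j] * x
  out
}

#' One two-channel analysis split
#'
#' Convolves the signal with the orthogonal low-pass and high-pass
#' decomposition filters (full convolution, zero extension) and decimates by
#' two, keeping the even-indexed phase. Each output has length
#' `ceiling((length(signal) + filter_length - 1) / 2)`. The analysis rows are
#' orthonormal, so energy is conserved exactly and [idwt_filter_merge()] (the
#' adjoint) reconstructs the input.
#'
#' @param signal numeric vector, at least as long as the filter.
#' @param wavelet_name one of `"db4"`, `"db2"`, `"haar"`.
#' @return list with components `low` and `high`.
#' @export
dwt_filter_split <- function(signal, wavelet_name = "db4") {
  f <- wavelet_filter(wavelet_name)
  if (length(signal) < length(f$lo))
    stop(errorCondition(sprintf("signal of length %d is shorter than the %d-tap filter",
                                length(signal), length(f$lo)),
                        class = c("ocuclean_decomposition_error", "error")))
  lo_full <- conv_full(signal, f$lo)
  hi_full <- conv_full(signal, f$hi)
  keep <- seq(1L, length(lo_full), by = 2L)
  list(low = lo_full[keep], high = hi_full[keep])
}

#' Inverse of [dwt_filter_split()] (adjoint reconstruction; used for testing)
#'
#' @param low,high coefficient vectors from [dwt_filter_split()].
#' @param n original signal length.
#' @param wavelet_name the wavelet used for the split.
#' @return numeric vector of length `n`.
#' @export
idwt_filter_merge <- function(low, high, n, wavelet_name = "db4") {
  f <- wavelet_filter(wavelet_name)
  m <- length(f$lo)
  up <- function(a) {
    u <- numeric(2L * length(a) - 1L)
    u[seq(1L, length(u), by = 2L)] <- a
    u
  }
  # x[t] = sum_k a[k] lo[2k - t] + d[k] hi[2k - t]  (0-based); realized as a
  # full convolution of the upsampled coefficients with the reversed filters.
  rec <- conv_full(up(low), rev(f$lo)) + conv_full(up(high), rev(f$hi))
  rec[m:(m + n - 1L)]
}

#' Five-level four-band wavelet decomposition
#'
#' Per level the current signal is split once into low/high, then each of the
#' two outputs is split again, yielding the four bands `LFLF`, `LFHF`, `HFLF`,
#' `HFHF`; the recursion continues on `LFLF` for five levels (20 coefficient
#' vectors in total).
#'
#' @param signal numeric vector; must be long enough to survive ten
#'   decimations (an error naming the maximum feasible depth is raised
#'   otherwise).
#' @param wavelet_name wavelet identifier.
#' @return an object of class `subband_set`: list with `levels` (5 entries of
#'   four named vectors), `wavelet_name`, `original_length`.
#' @export
dwt5_decompose <- function(signal, wavelet_name = "db4") {
  f <- wavelet_filter(wavelet_name)
  flen <- length(f$lo)
  levels <- vector("list", 5L)
  cur <- signal
  for (lev in 1:5) {
    if (length(cur) < flen || (lev > 1 && length(levels[[lev - 1L]]$LFLF) < flen))
      stop(errorCondition(
        sprintf("signal of length %d supports only %d levels of four-band decomposition",
                length(signal), lev - 1L),
        class = c("ocuclean_decomposition_error", "error")))
    s1 <- dwt_filter_split(cur, wavelet_name)
    slo <- dwt_filter_split(s1$low, wavelet_name)
    shi <- dwt_filter_split(s1$high, wavelet_name)
    levels[[lev]] <- list(LFLF = slo$low, LFHF = slo$high,
                          HFLF = shi$low, HFHF = shi$high)
    cur <- levels[[lev]]$LFLF
  }
  structure(list(levels = levels, wavelet_name = wavelet_name,
                 original_length = length(signal)),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> 5 levels x 4 bands, wavelet %s, input length %d\n",
              x$wavelet_name, x$original_length))
  for (lev in seq_along(x$levels))
    cat(sprintf("  level %d: band length %d\n", lev, length(x$levels[[lev]]$LFLF)))
  invisible(x)
}

#' Pisarenko harmonic analysis
#'
#' Builds the order-`model_order` sample autocorrelation (Toeplitz) matrix,
#' takes the eigenvector of its smallest eigenvalue (the noise eigenvector)
#' and evaluates the pseudospectrum `P(f) = 1 / |e(f)^H v_min|^2` on a regular
#' grid over `[0, 0.5)` cycles/sample. Dominant frequencies are the local
#' maxima of the pseudospectrum exceeding `median + 3 * MAD`.
#'
#' @param signal numeric vector.
#' @param model_order autocorrelation order `M` (>= 3, <= length/2).
#' @param grid_size number of frequency grid points.
#' @return an object of class `pisarenko_result`: list with `pseudospectrum`,
#'   `freq_grid`, `dominant_freqs`, `model_order`.
#' @export
pisarenko_analyze <- function(signal, model_order = 8, grid_size = 256) {
  model_order <- check_count(model_order, "model_order", min = 3L)
  grid_size <- check_count(grid_size, "grid_size", min = 8L)
  n <- length(signal)
  if (model_order > n / 2) stop_arg("`model_order` must be <= length(signal) / 2")
  if (all(signal == 0) || stats::var(signal) == 0)
    stop(errorCondition("signal has no variation; autocorrelation matrix is defective",
                        class = c("ocuclean_analysis_error", "error")))
  r <- vapply(0:(model_order - 1L), function(k) {
    mean(signal[1:(n - k)] * signal[(1 + k):n])
  }, numeric(1))
  R <- stats::toeplitz(r)
  eig <- eigen(R, symmetric = TRUE)
  v <- eig$vectors[, model_order]
  freq <- (seq_len(grid_size) - 1L) / (2 * grid_size)          # [0, 0.5)
  steer <- exp(-2i * pi * outer(freq, 0:(model_order - 1L)))   # G x M
  denom <- Mod(steer %*% v)^2
  p <- 1 / pmax(denom, 1e-300)
  thr <- stats::median(p) + 3 * stats::mad(p)
  g <- length(p)
  is_peak <- p > c(-Inf, p[-g]) & p >= c(p[-1], -Inf) & p > thr
  dominant <- freq[is_peak]
  dominant <- dominant[order(p[is_peak], decreasing = TRUE)]
  structure(list(pseudospectrum = as.numeric(p), freq_grid = freq,
                 dominant_freqs = dominant, model_order = model_order),
            class = "pisarenko_result")
}

# Marker for a subband too short for the requested Pisarenko order.
empty_pisarenko <- function() structure(list(empty = TRUE), class = "pisarenko_empty")

#' Is a per-subband Pisarenko slot empty?
#' @param x object returned inside [decompose_epoch()].
#' @export
is_empty_pisarenko <- function(x) inherits(x, "pisarenko_empty")

#' Decompose one epoch: wavelet cascade plus per-subband Pisarenko analysis
#'
#' @param epoch numeric vector (one channel of one epoch).
#' @param config list with optional entries `wavelet`, `pisarenko_order`,
#'   `pisarenko_grid`.
#' @return an object of class `decomposed_signal`: list with `subbands` (a
#'   `subband_set`) and `pisarenko` (20 entries in level-major band order,
#'   each a `pisarenko_result` or an empty marker for subbands shorter than
#'   twice the model order, or with no variation).
#' @export
decompose_epoch <- function(epoch, config = list()) {
  wavelet <- config$wavelet %||% "db4"
  order <- config$pisarenko_order %||% 8
  grid <- config$pisarenko_grid %||% 256
  sb <- dwt5_decompose(epoch, wavelet)
  ph <- list()
  for (lev in 1:5) {
    for (band in c("LFLF", "LFHF", "HFLF", "HFHF")) {
      x <- sb$levels[[lev]][[band]]
      key <- sprintf("L%d.%s", lev, band)
      ph[[key]] <- if (length(x) >= 2 * order && stats::var(x) > 0)
        pisarenko_analyze(x, order, grid) else empty_pisarenko()
    }
  }
  structure(list(subbands = sb, pisarenko = ph), class = "decomposed_signal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
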