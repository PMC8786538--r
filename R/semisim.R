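# Semisimulated EEG: seeded clean EEG generation, blink-like EOG contaminants
# and additive contamination with ground-truth labels. The default geometry is
# 25 channels (22 EEG + 3 EOG) x 1500 time points (250 Hz x 6 s) x 288 epochs.

#' Construct an epoch tensor
#'
#' The central data container of the package: a `channels x time x epochs`
#' array of microvolt samples together with the sampling rate, per-epoch
#' binary artifact labels and per-channel roles (`"EEG"` or `"EOG"`).
#'
#' @param data numeric array `[n_channels, n_timepoints, n_epochs]`.
#' @param fs sampling rate in Hz.
#' @param labels integer vector of 0/1 flags, one per epoch (1 = contaminated).
#' @param channel_roles character vector of `"EEG"`/`"EOG"` tags, one per channel.
#' @param artifact optional array of the same shape holding the added artifact
#'   component (zero on clean epochs); kept by [contaminate()] so the additive
#'   model can be verified exactly.
#' @param clean optional array of the same shape holding the clean target.
#' @return an object of class `epoch_tensor`.
#' @export
epoch_tensor <- function(data, fs, labels = NULL, channel_roles = NULL,
                         artifact = NULL, clean = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_arg("`data` must be a 3-d array [channels x time x epochs]")
  if (!all(is.finite(data))) stop_arg("`data` must be finite")
  fs <- check_positive(fs, "fs")
  d <- dim(data)
  if (is.null(labels)) labels <- integer(d[3L])
  if (length(labels) != d[3L]) stop_arg("`labels` length must equal n_epochs")
  if (!all(labels %in% c(0L, 1L))) stop_arg("`labels` must be binary")
  if (is.null(channel_roles)) channel_roles <- rep("EEG", d[1L])
  if (length(channel_roles) != d[1L] || !all(channel_roles %in% c("EEG", "EOG")))
    stop_arg("`channel_roles` must be 'EEG'/'EOG', one per channel")
  structure(list(data = data, fs = fs, labels = as.integer(labels),
                 channel_roles = channel_roles, artifact = artifact,
                 clean = clean),
            class = "epoch_tensor")
}

#' @export
print.epoch_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_tensor> %d channels (%d EEG, %d EOG) x %d time points x %d epochs @ %g Hz\n",
              d[1], sum(x$channel_roles == "EEG"), sum(x$channel_roles == "EOG"),
              d[2], d[3], x$fs))
  cat(sprintf("  contaminated epochs: %d / %d\n", sum(x$labels), d[3]))
  invisible(x)
}

#' Dimensions of an epoch tensor
#' @param x an `epoch_tensor`.
#' @export
dim.epoch_tensor <- function(x) dim(x$data)

# One clean epoch of one channel: band-limited oscillations plus 1/f noise.
# Amplitudes are in microvolts, in the range typical of scalp EEG.
clean_channel_epoch <- function(n, fs) {
  t <- seq_len(n) / fs
  sig <- numeric(n)
  bands <- list(theta = c(4, 8, 6), alpha = c(8, 13, 10), beta = c(13, 30, 4))
  for (b in bands) {
    for (k in 1:2) {
      f <- stats::runif(1, b[1], b[2])
      a <- b[3] * stats::runif(1, 0.5, 1.5)
      sig <- sig + a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
  }
  # 1/f ("pink") background via spectral shaping of white noise
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- c(1, seq_len(n - 1))              # avoid division by zero at DC
  shape <- 1 / sqrt(pmin(freqs, n - freqs + 1))
  pink <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink) * 5
  out <- sig + pink
  out - mean(out)
}

#' Generate clean synthetic multichannel EEG
#'
#' Every channel of every epoch is an independent seeded mixture of
#' band-limited oscillations (theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz,
#' two oscillators per band with randomized frequency, amplitude and phase)
#' plus 1/f background noise, made exactly zero-mean. Defaults reproduce the
#' evaluation geometry: 25 channels, 288 epochs of 6 s at 250 Hz.
#'
#' @param n_channels,n_epochs counts (>= 1).
#' @param fs sampling rate in Hz.
#' @param duration epoch duration in seconds; `fs * duration` must be integral.
#' @param seed integer master seed.
#' @param n_eog number of trailing channels tagged `"EOG"` (default 3 when
#'   `n_channels >= 4`, else 0). Clean EOG channels carry the same baseline
#'   signal model; blinks are only added by [contaminate()].
#' @return an `epoch_tensor` with all labels 0.
#' @export
generate_clean_eeg <- function(n_channels = 25, n_epochs = 288, fs = 250,
                               duration = 6, seed = 1,
                               n_eog = if (n_channels >= 4) 3L else 0L) {
  n_channels <- check_count(n_channels, "n_channels")
  n_epochs <- check_count(n_epochs, "n_epochs")
  fs <- check_positive(fs, "fs")
  duration <- check_positive(duration, "duration")
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9) stop_arg("`fs * duration` must be integral")
  n <- as.integer(round(n))
  n_eog <- check_count(n_eog, "n_eog", min = 0L)
  if (n_eog >= n_channels) stop_arg("`n_eog` must be < n_channels")

  data <- array(0, dim = c(n_channels, n, n_epochs))
  for (ch in seq_len(n_channels)) {
    data[ch, , ] <- with_seed(derive_seed(seed, "clean", ch), {
      vapply(seq_len(n_epochs), function(e) clean_channel_epoch(n, fs), numeric(n))
    })
  }
  roles <- c(rep("EEG", n_channels - n_eog), rep("EOG", n_eog))
  epoch_tensor(data, fs = fs, labels = integer(n_epochs), channel_roles = roles)
}

#' Generate a blink-like EOG waveform
#'
#' A sum of smooth unimodal pulses (squared half-sines of 200-400 ms width) at
#' Poisson-seeded random onsets, peak-normalized to 1 when at least one pulse
#' is present. This models the slow, large-amplitude deflection of an eye
#' blink as seen at frontal electrodes.
#'
#' @param fs sampling rate in Hz.
#' @param duration length of the waveform in seconds.
#' @param blink_rate expected blinks per second (>= 0).
#' @param seed integer seed.
#' @param min_pulses require at least this many pulses (used by
#'   [contaminate()] so a contaminated epoch always carries an artifact).
#' @return numeric vector of length `round(fs * duration)`.
#' @export
generate_eog_waveform <- function(fs, duration, blink_rate = 0.5, seed = 1,
                                  min_pulses = 0L) {
  fs <- check_positive(fs, "fs")
  duration <- check_positive(duration, "duration")
  if (!is.numeric(blink_rate) || blink_rate < 0) stop_arg("`blink_rate` must be >= 0")
  n <- as.integer(round(fs * duration))
  with_seed(seed, {
    k <- stats::rpois(1, blink_rate * duration)
    k <- max(k, min_pulses)
    w <- numeric(n)
    if (k > 0) {
      onsets <- stats::runif(k, 0, duration)
      widths <- stats::runif(k, 0.2, 0.4)
      for (i in seq_len(k)) {
        idx0 <- floor(onsets[i] * fs)
        m <- max(2L, as.integer(round(widths[i] * fs)))
        pulse <- sin(pi * seq_len(m) / (m + 1))^2
        lo <- idx0 + 1L
        hi <- min(n, idx0 + m)
        if (lo <= n) w[lo:hi] <- w[lo:hi] + pulse[seq_len(hi - lo + 1L)]
      }
      if (max(abs(w)) > 0) w <- w / max(abs(w))
    }
    attr(w, "n_pulses") <- k
    w
  })
}

#' Contamination specification
#'
#' @param snr positive clean-signal-power / added-artifact-power ratio within a
#'   contaminated epoch (power = time-domain mean square over EEG channels).
#' @param amplitude_ratio peak amplitude of the EOG reference-channel artifact
#'   relative to the clean EEG RMS; must lie in `[10, 100]` (ocular artifacts
#'   are 10-100x stronger than EEG).
#' @param artifact_fraction fraction of epochs to contaminate, in (0, 1].
#' @param blink_rate expected blinks per second within a contaminated epoch.
#' @param seed integer seed controlling epoch selection and blink timing.
#' @return a list of class `contamination_spec`.
#' @export
contamination_spec <- function(snr = 1.0, amplitude_ratio = 30,
                               artifact_fraction = 0.5, blink_rate = 0.5,
                               seed = 1) {
  snr <- check_positive(snr, "snr")
  if (!is.numeric(amplitude_ratio) || amplitude_ratio < 10 || amplitude_ratio > 100)
    stop_arg("`amplitude_ratio` must lie in [10, 100]")
  if (!is.numeric(artifact_fraction) || artifact_fraction <= 0 || artifact_fraction > 1)
    stop_arg("`artifact_fraction` must lie in (0, 1]")
  structure(list(snr = snr, amplitude_ratio = amplitude_ratio,
                 artifact_fraction = artifact_fraction,
                 blink_rate = blink_rate, seed = as.integer(seed)),
            class = "contamination_spec")
}

#' Add blink artifacts to a clean epoch tensor
#'
#' A seeded subset (`artifact_fraction`) of epochs receives an additive scaled
#' blink waveform: EEG channels get the leak scaled so that the per-epoch
#' clean-power / artifact-power ratio equals `spec$snr` (leak identical across
#' EEG channels; no spatial propagation model), and EOG channels get the
#' reference artifact with peak amplitude `amplitude_ratio` times the clean
#' EEG RMS. The clean target and the exact added artifact component are
#' retained in the result, so `contaminated - artifact == clean` elementwise.
#'
#' @param clean an `epoch_tensor` with all labels 0.
#' @param spec a [contamination_spec()].
#' @return an `epoch_tensor` with labels set on contaminated epochs and fields
#'   `artifact` (added component) and `clean` (the input data) filled in.
#' @export
contaminate <- function(clean, spec) {
  stopifnot(inherits(clean, "epoch_tensor"), inherits(spec, "contamination_spec"))
  if (any(clean$labels != 0L)) stop_arg("`clean` must have all labels 0")
  d <- dim(clean$data)
  n_epochs <- d[3L]
  n <- d[2L]
  eeg <- which(clean$channel_roles == "EEG")
  eog <- which(clean$channel_roles == "EOG")
  n_cont <- as.integer(round(spec$artifact_fraction * n_epochs))
  n_cont <- max(1L, n_cont)
  which_cont <- with_seed(derive_seed(spec$seed, "epochs"),
                          sort(sample.int(n_epochs, n_cont)))
  artifact <- array(0, dim = d)
  duration <- n / clean$fs
  for (e in which_cont) {
    w <- generate_eog_waveform(clean$fs, duration, spec$blink_rate,
                               seed = derive_seed(spec$seed, "blink", e),
                               min_pulses = 1L)
    clean_pow <- mean(clean$data[eeg, , e]^2)
    alpha <- sqrt(clean_pow / (spec$snr * mean(w^2)))
    for (ch in eeg) artifact[ch, , e] <- alpha * w
    if (length(eog)) {
      eog_amp <- spec$amplitude_ratio * sqrt(clean_pow)
      for (ch in eog) artifact[ch, , e] <- eog_amp * w
    }
  }
  labels <- integer(n_epochs)
  labels[which_cont] <- 1L
  epoch_tensor(clean$data + artifact, fs = clean$fs, labels = labels,
               channel_roles = clean$channel_roles, artifact = artifact,
               clean = clean$data)
}

#' Generate the default labelled semisimulated dataset
#'
#' Convenience wrapper: clean EEG in the default 25 x 1500 x 288 geometry plus
#' blink contamination, returning the contaminated tensor with its clean
#' target and artifact component attached.
#'
#' @param seed master seed.
#' @param snr,artifact_fraction,amplitude_ratio,blink_rate see
#'   [contamination_spec()].
#' @param n_channels,n_epochs,fs,duration see [generate_clean_eeg()].
#' @return an `epoch_tensor`.
#' @export
semisim_dataset <- function(seed = 1, snr = 1.0, artifact_fraction = 0.5,
                            amplitude_ratio = 30, blink_rate = 0.5,
                            n_channels = 25, n_epochs = 288, fs = 250,
                            duration = 6) {
  clean <- generate_clean_eeg(n_channels, n_epochs, fs, duration, seed = seed)
  contaminate(clean, contamination_spec(snr = snr,
                                        amplitude_ratio = amplitude_ratio,
                                        artifact_fraction = artifact_fraction,
                                        blink_rate = blink_rate,
                                        seed = derive_seed(seed, "contam")))
}
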