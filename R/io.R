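# File I/O: delimited-text serialization of epoch tensors and a minimal EDF
# (European Data Format) reader/writer for real multichannel recordings.

#' Write an epoch tensor to delimited text
#'
#' Two files are produced: `<base>_data.csv` (one row per channel x epoch:
#' `channel`, `epoch`, then the time samples) and `<base>_meta.csv` (sampling
#' rate, labels, channel roles).
#'
#' @param x an `epoch_tensor`.
#' @param base output path prefix.
#' @return `base`, invisibly.
#' @export
write_epoch_tensor <- function(x, base) {
  stopifnot(inherits(x, "epoch_tensor"))
  d <- dim(x$data)
  grid <- expand.grid(channel = seq_len(d[1]), epoch = seq_len(d[3]))
  rows <- t(vapply(seq_len(nrow(grid)), function(i)
    x$data[grid$channel[i], , grid$epoch[i]], numeric(d[2])))
  df <- data.frame(channel = grid$channel, epoch = grid$epoch, rows)
  names(df)[-(1:2)] <- paste0("t", seq_len(d[2]))
  data.table::fwrite(df, paste0(base, "_data.csv"))
  meta <- data.frame(
    key = c("fs", paste0("label_", seq_len(d[3])),
            paste0("role_", seq_len(d[1]))),
    value = c(x$fs, x$labels, x$channel_roles))
  data.table::fwrite(meta, paste0(base, "_meta.csv"))
  invisible(base)
}

#' Read an epoch tensor written by [write_epoch_tensor()]
#' @param base path prefix used when writing.
#' @return an `epoch_tensor`.
#' @export
read_epoch_tensor <- function(base) {
  df <- data.table::fread(paste0(base, "_data.csv"), data.table = FALSE)
  meta <- data.table::fread(paste0(base, "_meta.csv"), data.table = FALSE)
  n_ch <- max(df$channel); n_ep <- max(df$epoch)
  n_t <- ncol(df) - 2L
  data <- array(0, c(n_ch, n_t, n_ep))
  for (i in seq_len(nrow(df)))
    data[df$channel[i], , df$epoch[i]] <- as.numeric(df[i, -(1:2)])
  getv <- function(key) meta$value[meta$key == key]
  fs <- as.numeric(getv("fs"))
  labels <- as.integer(vapply(seq_len(n_ep),
                              function(e) getv(paste0("label_", e)), ""))
  roles <- vapply(seq_len(n_ch), function(c) getv(paste0("role_", c)), "")
  epoch_tensor(data, fs = fs, labels = labels, channel_roles = roles)
}

#' Segment a continuous multichannel recording into an epoch tensor
#'
#' @param signals numeric matrix `[channels x samples]`.
#' @param fs sampling rate in Hz.
#' @param duration epoch duration in seconds.
#' @param channel_roles optional per-channel roles.
#' @return an `epoch_tensor` (trailing partial epoch dropped).
#' @export
as_epoch_tensor <- function(signals, fs, duration = 6, channel_roles = NULL) {
  n <- as.integer(round(fs * duration))
  n_ep <- ncol(signals) %/% n
  if (n_ep < 1) stop_arg("recording shorter than one epoch")
  data <- array(0, c(nrow(signals), n, n_ep))
  for (e in seq_len(n_ep))
    data[, , e] <- signals[, ((e - 1L) * n + 1L):(e * n), drop = FALSE]
  epoch_tensor(data, fs = fs, channel_roles = channel_roles)
}

#' Read an EDF (European Data Format) recording
#'
#' Minimal reader for uncompressed EDF: parses the fixed 256-byte header and
#' the per-signal header fields, reads the 16-bit little-endian sample
#' records and rescales them to physical units. Annotation channels are not
#' interpreted; all signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return list with `signals` (`[channels x samples]` matrix in physical
#'   units), `fs`, `labels` (channel labels), `record_duration`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- rd(8)
  rd(80); rd(80); rd(8); rd(8)                  # patient, recording, date, time
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  record_duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16)
  fld(80); fld(8)                               # transducer, physical dimension
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                       # prefiltering
  nsamp <- as.integer(fld(8))
  fld(32)                                       # reserved
  if (length(unique(nsamp)) != 1L)
    stop_arg("signals with differing samples-per-record are not supported")
  per <- nsamp[1]
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- matrix(0, ns, n_records * per)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", per, size = 2L, signed = TRUE,
                     endian = "little")
      signals[s, ((r - 1L) * per + 1L):(r * per)] <-
        phys_min[s] + gain[s] * (raw - dig_min[s])
    }
  }
  list(signals = signals, fs = per / record_duration, labels = labels,
       record_duration = record_duration)
}

#' Write a multichannel recording as EDF
#'
#' Minimal writer (one data record per `record_duration`); used mainly to
#' round-trip-test the reader and to export simulated data for external
#' tools.
#'
#' @param signals numeric matrix `[channels x samples]` (physical units).
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @param labels optional channel labels.
#' @param record_duration seconds per data record.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, labels = NULL, record_duration = 1) {
  ns <- nrow(signals)
  per <- as.integer(round(fs * record_duration))
  n_records <- ncol(signals) %/% per
  if (n_records < 1) stop_arg("recording shorter than one data record")
  if (is.null(labels)) labels <- sprintf("CH%02d", seq_len(ns))
  phys_min <- apply(signals, 1L, min); phys_max <- apply(signals, 1L, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- rep(-32768L, ns); dig_max <- rep(32767L, ns)
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    writeBin(charToRaw(paste(substr(s, 1, w), collapse = "")), con)
  }
  header_bytes <- 256L + 256L * ns
  pad("0", 8); pad("X", 80); pad("X", 80)
  pad("01.01.26", 8); pad("00.00.00", 8)
  pad(header_bytes, 8); pad("", 44)
  pad(n_records, 8); pad(format(record_duration), 8); pad(ns, 4)
  for (s in labels) pad(s, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (v in phys_min) pad(formatC(v, digits = 6, format = "g"), 8)
  for (v in phys_max) pad(formatC(v, digits = 6, format = "g"), 8)
  for (v in dig_min) pad(v, 8)
  for (v in dig_max) pad(v, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(per, 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      x <- signals[s, ((r - 1L) * per + 1L):(r * per)]
      dig <- as.integer(round((x - phys_min[s]) / gain[s]) + dig_min[s])
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an input file into an epoch tensor, auto-detecting the format
#'
#' `.edf` files go through [read_edf()] and are segmented into epochs;
#' `<base>` prefixes of the package's CSV pair go through
#' [read_epoch_tensor()].
#'
#' @param path input path (EDF file or CSV base prefix).
#' @param fs,duration segmentation parameters for continuous formats.
#' @return an `epoch_tensor`.
#' @export
read_input <- function(path, fs = NULL, duration = 6) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
    as_epoch_tensor(rec$signals, rec$fs, duration)
  } else {
    read_epoch_tensor(sub("_data\\.csv$", "", path))
  }
}
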