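#' Quantize a signal onto a uniform ADC grid
#'
#' Reproduces the on-device analog-to-digital conversion: `2^n_bits`
#' uniformly spaced levels spanning the symmetric range
#' `[-full_scale, full_scale]` (both end levels included). Values are
#' rounded to the nearest level; values outside the range clip to the
#' extreme levels. The operation is idempotent and monotone.
#'
#' @param signal numeric vector or matrix of voltages (microvolts). For a
#'   matrix, rows are channels.
#' @param n_bits ADC bit depth (device default 10).
#' @param full_scale half-range of the converter in microvolts; the grid
#'   spans `[-full_scale, full_scale]`.
#' @return quantized object of the same shape as `signal`.
#' @export
quantize_adc <- function(signal, n_bits = IEEG_ADC_BITS,
                         full_scale = IEEG_FULL_SCALE) {
  stopifnot(is.numeric(n_bits), length(n_bits) == 1L, n_bits >= 1,
            is.numeric(full_scale), length(full_scale) == 1L,
            is.finite(full_scale), full_scale > 0)
  bad <- which(!is.finite(signal))
  if (length(bad)) {
    i <- bad[1L]
    if (is.matrix(signal)) {
      stop_fmt("non-finite sample in channel %d at index %d",
               row(signal)[i], col(signal)[i])
    }
    stop_fmt("non-finite sample at index %d", i)
  }
  n_levels <- 2^n_bits
  pmin_ <- -full_scale
  step <- 2 * full_scale / (n_levels - 1)
  idx <- round((signal - pmin_) / step)
  idx[idx < 0] <- 0
  idx[idx > n_levels - 1] <- n_levels - 1
  out <- pmin_ + idx * step
  attributes(out) <- attributes(signal)
  out
}

#' Construct and validate an iEEG epoch
#'
#' One fixed-duration, 4-channel RNS recording: 90 s at 250 Hz
#' (22,500 samples per channel), microvolt units.
#'
#' @param samples numeric matrix, 4 channels x 22,500 samples.
#' @param patient_id opaque patient identifier.
#' @param recorded_at POSIXct acquisition timestamp.
#' @param trigger `"scheduled"` (device clock) or `"detection"`
#'   (onboard detector).
#' @param channel_names four bipolar-derivation labels.
#' @param sampling_rate,duration acquisition constants; fixed at 250 Hz
#'   and 90 s and validated.
#' @return an object of class `ieeg_epoch`.
#' @export
ieeg_epoch <- function(samples, patient_id, recorded_at,
                       trigger = "scheduled",
                       channel_names = paste0("ch", 1:4, "-", 2:5),
                       sampling_rate = IEEG_FS, duration = IEEG_DURATION) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_fmt("samples must be a numeric matrix")
  if (nrow(samples) != IEEG_CHANNELS)
    stop_fmt("channel count must be %d, got %d", IEEG_CHANNELS, nrow(samples))
  if (sampling_rate != IEEG_FS)
    stop_fmt("sampling_rate must be %d Hz, got %s", IEEG_FS, sampling_rate)
  if (duration != IEEG_DURATION)
    stop_fmt("duration must be %d s, got %s", IEEG_DURATION, duration)
  if (ncol(samples) != IEEG_SAMPLES)
    stop_fmt("samples per channel must be %d, got %d",
             IEEG_SAMPLES, ncol(samples))
  if (any(!is.finite(samples))) stop_fmt("samples contain non-finite values")
  trigger <- match.arg(trigger, TRIGGER_TYPES)
  stopifnot(length(channel_names) == IEEG_CHANNELS)
  if (!inherits(recorded_at, "POSIXct"))
    recorded_at <- as.POSIXct(recorded_at, tz = "UTC")
  structure(list(samples = samples,
                 sampling_rate = IEEG_FS, duration = IEEG_DURATION,
                 patient_id = as.character(patient_id),
                 recorded_at = recorded_at, trigger = trigger,
                 channel_names = as.character(channel_names)),
            class = "ieeg_epoch")
}

#' Construct an ictal-onset annotation
#'
#' @param s binary ictal label: 1 when the epoch contains an ictal pattern.
#' @param t onset time in seconds from epoch start; required (and only
#'   defined) when `s = 1`, with `0 <= t < 90`. Stored with millisecond
#'   precision.
#' @return an object of class `onset_annotation`.
#' @export
onset_annotation <- function(s, t = NA_real_) {
  if (!s %in% c(0, 1)) stop_fmt("label s must be 0 or 1")
  if (s == 1) {
    if (!is.finite(t)) stop_fmt("onset t is required when s = 1")
    if (t < 0 || t >= IEEG_DURATION)
      stop_fmt("onset t must lie in [0, %d), got %s", IEEG_DURATION, t)
    t <- round(t, 3)
  } else {
    t <- NA_real_
  }
  structure(list(s = as.integer(s), t = t), class = "onset_annotation")
}

## ---- minimal EDF container ----------------------------------------------
## EDF (not EDF+) with a single 90-s data record; onset labels travel in a
## CSV sidecar because they are per-epoch scalars, not in-stream events.
## Physical min/max are written as exact integers so that the
## digital<->physical mapping round-trips quantized samples bit-exactly.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(path, samples, fs, channel_names, phys_min, phys_max,
                      dig_min, dig_max, start, patient_field, recording_field) {
  ns <- nrow(samples)
  n_samp <- ncol(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(patient_field, 80),
    edf_pad(recording_field, 80),
    edf_pad(format(start, "%d.%m.%y"), 8),
    edf_pad(format(start, "%H.%M.%S"), 8),
    edf_pad(256 + ns * 256, 8),
    edf_pad("", 44),
    edf_pad(1, 8),
    edf_pad(n_samp / fs, 8),
    edf_pad(ns, 4))
  sig <- paste0(
    paste(vapply(channel_names, edf_pad, "", width = 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(phys_max, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_min, 8), ns), collapse = ""),
    paste(rep(edf_pad(dig_max, 8), ns), collapse = ""),
    paste(rep(edf_pad("BP:4-125Hz", 80), ns), collapse = ""),
    paste(rep(edf_pad(n_samp, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL, useBytes = TRUE)
  step <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round((t(samples) - phys_min) / step) + dig_min
  dig[dig < dig_min] <- dig_min
  dig[dig > dig_max] <- dig_max
  writeBin(as.integer(dig), con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  patient_field <- trimws(rd(80))
  recording_field <- trimws(rd(80))
  date <- rd(8); time <- rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)                      # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)                      # prefiltering
  n_samp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  samples <- matrix(0, ns, n_samp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = n_samp[i], size = 2L,
                   endian = "little")
      # same expression form as quantize_adc's grid (pmin + k * step) so
      # quantized samples round-trip bit-exactly
      step <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      x <- phys_min[i] + (d - dig_min[i]) * step
      samples[i, ((r - 1) * n_samp[i] + 1):(r * n_samp[i])] <- x
    }
  }
  start <- as.POSIXct(paste(date, time), format = "%d.%m.%y %H.%M.%S",
                      tz = "UTC")
  list(samples = samples, fs = n_samp[1] / rec_dur, labels = labels,
       dims = dims, start = start, patient_field = patient_field,
       recording_field = recording_field)
}

sidecar_path <- function(path) sub("\\.edf$", ".csv", path)

#' Write one epoch to disk (EDF + CSV sidecar)
#'
#' The 4 signals go into an EDF file with sampling-rate, channel-label and
#' physical-dimension headers; the annotation goes into a one-row CSV
#' sidecar (`epoch_id, patient_id, recorded_at, trigger, s, t_seconds`).
#' Samples are quantized onto the 10-bit ADC grid before writing, which
#' makes the EDF round trip exact.
#'
#' @param epoch an [ieeg_epoch()].
#' @param annotation an [onset_annotation()].
#' @param path output EDF path (`.edf`); the sidecar replaces the
#'   extension with `.csv`.
#' @param full_scale ADC half-range in microvolts.
#' @return `path`, invisibly.
#' @export
write_epoch <- function(epoch, annotation, path,
                        full_scale = IEEG_FULL_SCALE) {
  stopifnot(inherits(epoch, "ieeg_epoch"),
            inherits(annotation, "onset_annotation"))
  if (!grepl("\\.edf$", path)) path <- paste0(path, ".edf")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  q <- quantize_adc(epoch$samples, full_scale = full_scale)
  n_levels <- 2^IEEG_ADC_BITS
  write_edf(path, q, fs = epoch$sampling_rate,
            channel_names = epoch$channel_names,
            phys_min = -full_scale, phys_max = full_scale,
            dig_min = 0, dig_max = n_levels - 1,
            start = epoch$recorded_at,
            patient_field = epoch$patient_id,
            recording_field = paste0("trigger:", epoch$trigger))
  epoch_id <- sub("\\.edf$", "", basename(path))
  df <- data.frame(
    epoch_id = epoch_id, patient_id = epoch$patient_id,
    recorded_at = format(epoch$recorded_at, "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
    trigger = epoch$trigger, s = annotation$s,
    t_seconds = if (annotation$s == 1) annotation$t else NA_real_,
    stringsAsFactors = FALSE)
  write.csv(df, sidecar_path(path), row.names = FALSE, na = "")
  invisible(path)
}

#' Read one epoch written by [write_epoch()]
#'
#' Validates the RNS acquisition conventions on ingestion: exactly 4
#' channels, 250 Hz, 22,500 samples per channel; annotation fields are
#' bounds-checked.
#'
#' @param path EDF path; the CSV sidecar is looked up next to it.
#' @return `list(epoch = <ieeg_epoch>, annotation = <onset_annotation>)`.
#' @export
read_epoch <- function(path) {
  if (!file.exists(path)) stop_fmt("no such file: %s", path)
  e <- read_edf(path)
  if (nrow(e$samples) != IEEG_CHANNELS)
    stop_fmt("format error: channel count is %d, expected %d",
             nrow(e$samples), IEEG_CHANNELS)
  if (abs(e$fs - IEEG_FS) > 1e-9)
    stop_fmt("format error: sampling rate is %s Hz, expected %d",
             format(e$fs), IEEG_FS)
  if (ncol(e$samples) != IEEG_SAMPLES)
    stop_fmt("format error: samples per channel is %d, expected %d",
             ncol(e$samples), IEEG_SAMPLES)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop_fmt("missing CSV sidecar: %s", side)
  df <- read.csv(side, stringsAsFactors = FALSE)
  need <- c("epoch_id", "patient_id", "recorded_at", "trigger", "s",
            "t_seconds")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_fmt("sidecar missing column(s): %s",
                             paste(miss, collapse = ", "))
  epoch_id <- sub("\\.edf$", "", basename(path))
  row <- df[df$epoch_id == epoch_id, , drop = FALSE]
  if (nrow(row) != 1L)
    stop_fmt("sidecar has %d rows for epoch id '%s'", nrow(row), epoch_id)
  ann <- onset_annotation(row$s, if (row$s == 1) row$t_seconds else NA_real_)
  epoch <- ieeg_epoch(e$samples, patient_id = row$patient_id,
                      recorded_at = as.POSIXct(row$recorded_at,
                                               format = "%Y-%m-%dT%H:%M:%S",
                                               tz = "UTC"),
                      trigger = row$trigger, channel_names = e$labels)
  list(epoch = epoch, annotation = ann)
}
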