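## Synthetic RNS-style cohort: interictal background, evolving ictal
## patterns with known onsets, and the main detector-confound classes.
## The generator's goal is detectability and onset recoverability on a
## known ground truth, not electrophysiological realism.

MIN_SEIZURE_DURATION <- 10   # s; shortest non-confound ictal discharge

#' Create a per-patient generative profile
#'
#' Deterministic function of `(patient_index, master_seed)`: the same pair
#' always yields the same profile, and distinct patients receive distinct
#' seizure morphologies (onset/terminal frequency, growth, channel
#' involvement), which is what makes patient conditioning learnable.
#'
#' @param patient_index positive integer.
#' @param implant_site one of `r paste(IMPLANT_SITES, collapse = ", ")`.
#' @param master_seed integer master seed.
#' @return an object of class `patient_profile`.
#' @export
make_patient_profile <- function(patient_index,
                                 implant_site = "hippocampus",
                                 master_seed = 1) {
  stopifnot(patient_index >= 1)
  implant_site <- match.arg(implant_site, IMPLANT_SITES)
  seed <- derive_seed(master_seed, paste0("profile:", patient_index))
  with_seed(seed, {
    n_inv <- sample(2:4, 1)
    mix <- stats::setNames(numeric(length(CONFOUND_CLASSES)),
                           CONFOUND_CLASSES)
    structure(list(
      patient_id = sprintf("P%02d", patient_index),
      implant_site = implant_site,
      background_params = local({
        slope <- runif(1, 1.2, 1.8)                # 1/f^alpha exponent
        rms <- runif(1, 20, 40)
        rate <- runif(1, 2, 8)
        # spikes are prominent relative to this patient's background
        list(spectral_slope = slope, rms_uv = rms,
             spike_rate_per_min = rate,
             spike_amp_uv = rms * runif(1, 4, 7))
      }),
      seizure_params = list(
        onset_freq_hz = runif(1, 14, 30),          # fast low-voltage start
        terminal_freq_hz = runif(1, 4, 8),         # rhythmic slowing
        amplitude_growth = runif(1, 3, 6),         # ictal RMS / background RMS
        channel_mask = sort(sample(1:4, n_inv)),
        mean_duration_s = runif(1, 30, 50)),
      confound_mix = mix,
      rng_seed = seed), class = "patient_profile")
  })
}

## band-limited 1/f^alpha noise, one channel, zero-phase (FFT) filtering
colored_noise <- function(n, alpha, fs = IEEG_FS, band = IEEG_BAND,
                          rms = 1) {
  x <- rnorm(n)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  gain <- ifelse(f >= band[1] & f <= band[2], f^(-alpha / 2), 0)
  y <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
  y * rms / sqrt(mean(y^2))
}

## short biphasic interictal transient (Gabor-like), returns a waveform
spike_wave <- function(fs = IEEG_FS, amp = 1) {
  t <- seq(-0.08, 0.08, by = 1 / fs)
  amp * sin(2 * pi * 10 * t) * exp(-(t / 0.03)^2)
}

add_spikes <- function(samples, rate_per_min, amp_uv, fs = IEEG_FS) {
  n_min <- ncol(samples) / fs / 60
  n_sp <- rpois(1, rate_per_min * n_min)
  if (n_sp == 0) return(samples)
  w <- spike_wave(fs)
  for (i in seq_len(n_sp)) {
    at <- sample.int(ncol(samples) - length(w), 1)
    chans <- sample(1:4, sample(1:3, 1))
    a <- amp_uv * runif(1, 0.7, 1.3) * sample(c(-1, 1), 1)
    idx <- at:(at + length(w) - 1)
    samples[chans, idx] <- samples[chans, idx] +
      matrix(rep(a * w, each = length(chans)), nrow = length(chans))
  }
  samples
}

#' Generate a 90-s interictal (non-ictal) background
#'
#' Band-limited `1/f^alpha` colored noise per channel at the profile's RMS
#' amplitude, with sporadic interictal spikes at the profile rate. This is
#' the non-ictal class: activity between seizures.
#'
#' @param profile a [make_patient_profile()] object.
#' @param spike_rate optional override of the profile spike rate
#'   (events/min).
#' @param rms_scale multiplier on the profile background RMS.
#' @return 4 x 22,500 numeric matrix (microvolts, unquantized).
#' @export
generate_background <- function(profile, spike_rate = NULL, rms_scale = 1) {
  bp <- profile$background_params
  samples <- t(vapply(1:4, function(ch)
    colored_noise(IEEG_SAMPLES, bp$spectral_slope,
                  rms = bp$rms_uv * rms_scale * runif(1, 0.9, 1.1)),
    numeric(IEEG_SAMPLES)))
  add_spikes(samples, spike_rate %||% bp$spike_rate_per_min, bp$spike_amp_uv)
}

## chirp-like ictal discharge: frequency sweeps onset -> terminal while the
## amplitude ramps to growth x background RMS; mild second-harmonic
## distortion and slow amplitude modulation stand in for morphology
## evolution. Returns a length-n waveform for one channel.
ictal_wave <- function(n, f0, f1, amp, fs = IEEG_FS) {
  tau <- (seq_len(n) - 1) / fs
  dur <- n / fs
  phase <- 2 * pi * (f0 * tau + (f1 - f0) / (2 * dur) * tau^2) +
    runif(1, 0, 2 * pi)
  ramp <- pmin(tau / 3, 1)                       # 3-s recruitment ramp
  taper <- pmin((dur - tau) / 1.5, 1)            # 1.5-s offset taper
  am <- 1 + 0.3 * sin(2 * pi * 0.4 * tau + runif(1, 0, 2 * pi))
  amp * ramp * taper * am * (sin(phase) + 0.3 * sin(2 * phase))
}

#' Generate an ictal epoch with a known onset
#'
#' Background as in [generate_background()]; from `onset` onwards the
#' profile's involved channels carry a chirp-like oscillation sweeping the
#' onset frequency towards the terminal frequency with growing amplitude.
#' The annotation's `t` equals the requested onset exactly.
#'
#' @param profile a [make_patient_profile()] object.
#' @param onset seconds from epoch start; needs
#'   `onset + 10 s <= 90 s` so a minimal discharge fits.
#' @param duration optional discharge duration (s); drawn from the profile
#'   when `NULL`.
#' @param channel_mask optional override of the involved channels.
#' @param decrement_s optional electro-decrement length (s): signal
#'   amplitude drops to a fraction of baseline right after onset before
#'   the oscillation emerges.
#' @return `list(samples, annotation)`: matrix plus [onset_annotation()].
#' @export
generate_ictal_epoch <- function(profile, onset, duration = NULL,
                                 channel_mask = NULL, decrement_s = 0) {
  if (!is.finite(onset) || onset < 0 || onset >= IEEG_DURATION)
    stop_fmt("onset must lie in [0, %d)", IEEG_DURATION)
  if (onset + MIN_SEIZURE_DURATION > IEEG_DURATION)
    stop_fmt("onset %.1f leaves no room for a %.0f-s discharge",
             onset, MIN_SEIZURE_DURATION)
  sp <- profile$seizure_params
  bp <- profile$background_params
  mask <- channel_mask %||% sp$channel_mask
  samples <- generate_background(profile)
  dur <- duration %||% max(MIN_SEIZURE_DURATION,
                           rnorm(1, sp$mean_duration_s, 5))
  dur <- min(dur, IEEG_DURATION - onset)
  i0 <- floor(onset * IEEG_FS) + 1L
  if (decrement_s > 0) {
    # electro-decrement: amplitude falls to near-baseline flatness first
    idec <- i0:min(i0 + round(decrement_s * IEEG_FS) - 1L, IEEG_SAMPLES)
    samples[, idec] <- samples[, idec] * 0.15
    i0 <- min(idec[length(idec)] + 1L, IEEG_SAMPLES)
    dur <- dur - decrement_s
  }
  n <- min(round(dur * IEEG_FS), IEEG_SAMPLES - i0 + 1L)
  if (n > 0) {
    # 0.74 = RMS of the unit chirp waveform (sin + 0.3 * second harmonic),
    # so the added discharge has RMS ~ growth x background RMS at plateau
    amp <- sp$amplitude_growth * bp$rms_uv / 0.74
    for (ch in mask) {
      w <- ictal_wave(n, sp$onset_freq_hz * runif(1, 0.95, 1.05),
                      sp$terminal_freq_hz, amp * runif(1, 0.85, 1.15))
      samples[ch, i0:(i0 + n - 1L)] <- samples[ch, i0:(i0 + n - 1L)] + w
    }
  }
  list(samples = samples, annotation = onset_annotation(1, onset),
       duration = dur + decrement_s)
}

#' Generate one detector-confound epoch
#'
#' Implements the main classes of conditions known to defeat CNN seizure
#' detectors: ictal electro-decrements, brief ictal patterns, ictal
#' patterns isolated to one channel, dense interictal activity, and
#' abrupt sleep-wake (arousal) background transitions.
#'
#' @param profile a [make_patient_profile()] object.
#' @param category one of
#'   `r paste(CONFOUND_CLASSES, collapse = ", ")`.
#' @return `list(samples, annotation)`; `s = 1` for the first three
#'   classes, `s = 0` for the last two.
#' @export
generate_confound_epoch <- function(profile, category) {
  if (!category %in% CONFOUND_CLASSES)
    stop_fmt("unknown confound category '%s'", category)
  switch(category,
    electrodecrement_onset = {
      onset <- runif(1, 5, 40)
      generate_ictal_epoch(profile, onset, decrement_s = runif(1, 3, 5))
    },
    brief_ictal = {
      dur <- runif(1, 3, 8)
      onset <- runif(1, 5, IEEG_DURATION - dur - 2)
      out <- generate_ictal_epoch(profile, onset, duration = dur)
      out
    },
    single_channel_ictal = {
      onset <- runif(1, 5, 50)
      generate_ictal_epoch(profile, onset,
                           channel_mask = sample(1:4, 1))
    },
    dense_interictal = {
      rate <- max(10 * profile$background_params$spike_rate_per_min, 20)
      s <- generate_background(profile, spike_rate = rate)
      list(samples = s, annotation = onset_annotation(0))
    },
    arousal_transition = {
      step_at <- runif(1, 30, 60)
      i <- round(step_at * IEEG_FS)
      asleep <- generate_background(profile, rms_scale = 0.6)
      bp <- profile$background_params
      awake <- t(vapply(1:4, function(ch)
        colored_noise(IEEG_SAMPLES, max(bp$spectral_slope - 0.5, 0.5),
                      rms = bp$rms_uv * 1.6), numeric(IEEG_SAMPLES)))
      s <- cbind(asleep[, 1:i, drop = FALSE],
                 awake[, (i + 1):IEEG_SAMPLES, drop = FALSE])
      list(samples = s, annotation = onset_annotation(0))
    })
}

#' Cohort generation configuration
#'
#' @param n_patients number of synthetic patients.
#' @param epochs_per_patient epochs per patient.
#' @param ictal_fraction fraction of epochs containing an ictal pattern.
#' @param scheduled_fraction probability that a non-ictal epoch is a
#'   scheduled (clock-triggered) recording; these supply the interictal
#'   pairing pool for seed sets.
#' @param confound_fraction fraction of epochs replaced by confound
#'   epochs (drawn from the profile's `confound_mix`; 0 disables).
#' @param start_date,span_days timestamp window for the recordings.
#' @param master_seed integer; the cohort is a pure function of the
#'   configuration including this seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 6, epochs_per_patient = 60,
                          ictal_fraction = 0.4, scheduled_fraction = 0.7,
                          confound_fraction = 0,
                          start_date = as.POSIXct("2021-01-01",
                                                  tz = "UTC"),
                          span_days = 180, master_seed = 1) {
  stopifnot(n_patients >= 1, epochs_per_patient >= 1,
            ictal_fraction >= 0, ictal_fraction <= 1,
            scheduled_fraction >= 0, scheduled_fraction <= 1,
            confound_fraction >= 0, confound_fraction <= 1)
  if (!inherits(start_date, "POSIXct"))
    start_date <- as.POSIXct(start_date, tz = "UTC")   # e.g. from YAML
  structure(list(n_patients = as.integer(n_patients),
                 epochs_per_patient = as.integer(epochs_per_patient),
                 ictal_fraction = ictal_fraction,
                 scheduled_fraction = scheduled_fraction,
                 confound_fraction = confound_fraction,
                 start_date = start_date, span_days = span_days,
                 master_seed = as.integer(master_seed)),
            class = "cohort_config")
}

#' Generate a multi-patient synthetic cohort
#'
#' Per patient: `epochs_per_patient` epochs at the configured ictal
#' fraction, strictly increasing timestamps, detection triggers for ictal
#' epochs and scheduled/detection triggers for non-ictal ones. Fully
#' reproducible from `config$master_seed`. Samples are quantized onto the
#' 10-bit ADC grid.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, every epoch is
#'   written through [write_epoch()] and a `manifest.csv` plus a cohort
#'   `annotations.csv` are emitted.
#' @param sites implant sites cycled over patients.
#' @return an in-memory cohort: list with `epochs` (list of
#'   [ieeg_epoch()]), `annotations` (data.frame), `profiles`, `metadata`
#'   (per-patient [load_cohort_table()]-style rows) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL,
                            sites = c("hippocampus",
                                      "developmental_malformation",
                                      "neocortex")) {
  stopifnot(inherits(config, "cohort_config"))
  epochs <- list()
  ann <- list()
  profiles <- list()
  meta <- list()
  # Onset placement model: detection-triggered clips hold ~30 s of
  # pre-trigger signal and the onboard detector fires within seconds of
  # electrographic onset, so most onsets sit just below the pre-trigger
  # depth; a minority of seizures are caught by scheduled recordings at
  # arbitrary positions. Discharges continue to the end of the clip.
  pre_trigger_s <- 30
  draw_onset <- function() {
    if (runif(1) < 0.9)
      max(2, min(pre_trigger_s, pre_trigger_s - rgamma(1, shape = 2,
                                                       scale = 2)))
    else runif(1, 5, 50)
  }
  for (p in seq_len(config$n_patients)) {
    site <- sites[(p - 1) %% length(sites) + 1]
    prof <- make_patient_profile(p, site, config$master_seed)
    profiles[[prof$patient_id]] <- prof
    seed <- derive_seed(config$master_seed, paste0("cohort:", p))
    with_seed(seed, {
      ne <- config$epochs_per_patient
      n_ict <- round(ne * config$ictal_fraction)
      is_ictal <- logical(ne)
      is_ictal[sample.int(ne, n_ict)] <- TRUE
      ts <- config$start_date +
        sort(runif(ne, 0, config$span_days * 86400)) + seq_len(ne) * 1e-3
      for (j in seq_len(ne)) {
        use_confound <- runif(1) < config$confound_fraction
        mix <- prof$confound_mix
        if (use_confound && sum(mix) > 0) {
          cls <- sample(names(mix), 1, prob = mix)
          gen <- generate_confound_epoch(prof, cls)
          # keep the epoch consistent with the drawn label
          if ((gen$annotation$s == 1) != is_ictal[j]) {
            gen <- if (is_ictal[j]) {
              on <- draw_onset()
              generate_ictal_epoch(prof, on, duration = IEEG_DURATION - on)
            } else list(samples = generate_background(prof),
                        annotation = onset_annotation(0))
          }
        } else if (is_ictal[j]) {
          on <- draw_onset()
          gen <- generate_ictal_epoch(prof, on,
                                      duration = IEEG_DURATION - on)
        } else {
          gen <- list(samples = generate_background(prof),
                      annotation = onset_annotation(0))
        }
        trig <- if (gen$annotation$s == 1) "detection"
                else if (runif(1) < config$scheduled_fraction) "scheduled"
                else "detection"
        eid <- sprintf("%s_e%04d", prof$patient_id, j)
        ep <- ieeg_epoch(quantize_adc(gen$samples),
                         patient_id = prof$patient_id,
                         recorded_at = ts[j], trigger = trig)
        epochs[[eid]] <- ep
        ann[[eid]] <- data.frame(
          epoch_id = eid, patient_id = prof$patient_id,
          recorded_at = format(ts[j], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
          trigger = trig, s = gen$annotation$s,
          t_seconds = gen$annotation$t, stringsAsFactors = FALSE)
      }
      meta[[p]] <- data.frame(
        patient = prof$patient_id,
        age = sample(18:65, 1),
        gender = sample(c("F", "M"), 1),
        implantation_site = site,
        n_days = as.integer(round(config$span_days)),
        n_ieeg_files = ne, n_ictal_patterns = n_ict,
        stringsAsFactors = FALSE)
    })
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  metadata <- do.call(rbind, meta)
  class(metadata) <- c("recording_metadata", "data.frame")
  cohort <- structure(list(epochs = epochs, annotations = annotations,
                           profiles = profiles, metadata = metadata,
                           config = config),
                      class = "ieeg_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort to disk in the EDF + CSV layout
#' @param cohort an `ieeg_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (eid in names(cohort$epochs)) {
    row <- cohort$annotations[cohort$annotations$epoch_id == eid, ]
    ann <- onset_annotation(row$s, if (row$s == 1) row$t_seconds else NA)
    write_epoch(cohort$epochs[[eid]], ann,
                file.path(dir, row$patient_id, paste0(eid, ".edf")))
  }
  write.csv(cohort$annotations, file.path(dir, "annotations.csv"),
            row.names = FALSE, na = "")
  agg <- cohort$metadata
  manifest <- data.frame(patient = agg$patient,
                         implant_site = agg$implantation_site,
                         n_epochs = agg$n_ieeg_files,
                         n_ictal = agg$n_ictal_patterns)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(agg, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a cohort previously written by [write_cohort()]
#' @param dir cohort directory.
#' @return an `ieeg_cohort` (without generative profiles).
#' @export
load_cohort <- function(dir) {
  ann_path <- file.path(dir, "annotations.csv")
  if (!file.exists(ann_path)) stop_fmt("not a cohort directory: %s", dir)
  annotations <- read.csv(ann_path, stringsAsFactors = FALSE)
  epochs <- list()
  for (i in seq_len(nrow(annotations))) {
    row <- annotations[i, ]
    p <- file.path(dir, row$patient_id, paste0(row$epoch_id, ".edf"))
    epochs[[row$epoch_id]] <- read_epoch(p)$epoch
  }
  metadata <- read.csv(file.path(dir, "metadata.csv"),
                       stringsAsFactors = FALSE)
  class(metadata) <- c("recording_metadata", "data.frame")
  structure(list(epochs = epochs, annotations = annotations,
                 profiles = NULL, metadata = metadata, config = NULL),
            class = "ieeg_cohort")
}
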