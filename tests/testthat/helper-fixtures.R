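# Shared fixtures, generated in code. Heavier objects are memoised in this
# environment so that the suite builds them once.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

test_profile <- function(index = 1, seed = 101) {
  make_patient_profile(index, "hippocampus", master_seed = seed)
}

# random but valid epoch matrix on the ADC grid
test_samples <- function(seed = 1, sd = 30) {
  set.seed(seed)
  quantize_adc(matrix(rnorm(4 * 22500, sd = sd), 4))
}

test_epoch <- function(seed = 1, trigger = "scheduled") {
  ieeg_epoch(test_samples(seed), patient_id = "P01",
             recorded_at = as.POSIXct("2021-06-01 12:00:00", tz = "UTC"),
             trigger = trigger)
}

# small shared cohort for training/evaluation tests
small_cohort <- function() {
  memo("small_cohort", function()
    generate_cohort(cohort_config(n_patients = 3, epochs_per_patient = 16,
                                  ictal_fraction = 0.5, master_seed = 202)))
}

tiny_spec <- function(n_patients, ...) {
  network_spec(n_patients = n_patients, first_filters = 3,
               penultimate_filters = 9, ...)
}

# per-1-second-window RMS of one channel
windowed_rms <- function(x, fs = 250) {
  n <- floor(length(x) / fs)
  vapply(seq_len(n), function(i) {
    seg <- x[((i - 1) * fs + 1):(i * fs)]
    sqrt(mean(seg^2))
  }, numeric(1))
}

# independent AUPRC oracle: exhaustive threshold enumeration over the
# step-shaped precision-recall curve
auprc_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(th, function(cut) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1)
    c(recall = tp / sum(labels == 1), precision = tp / sum(pred))
  }, numeric(2)))
  r <- c(0, pts[, "recall"])
  sum(diff(r) * pts[, "precision"])
}
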