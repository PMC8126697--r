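test_that("patient profiles are deterministic, distinct and in-band", {
  p1 <- make_patient_profile(1, "neocortex", 7)
  p1b <- make_patient_profile(1, "neocortex", 7)
  expect_identical(p1, p1b)
  p2 <- make_patient_profile(2, "neocortex", 7)
  expect_false(identical(p1$seizure_params, p2$seizure_params))

  for (i in 1:300) {
    p <- make_patient_profile(i %% 40 + 1, master_seed = i)
    sp <- p$seizure_params
    expect_gte(sp$onset_freq_hz, 4); expect_lte(sp$onset_freq_hz, 125)
    expect_gte(sp$terminal_freq_hz, 4); expect_lte(sp$terminal_freq_hz, 125)
    expect_gte(length(sp$channel_mask), 1)
    expect_true(all(p$confound_mix >= 0) && sum(p$confound_mix) <= 1)
  }
})

test_that("background is band-limited colored noise with controllable spikes", {
  prof <- test_profile()
  set.seed(11)
  bg <- generate_background(prof, spike_rate = 0)
  # no transients: at most stray Gaussian-tail samples beyond 5x RMS
  for (ch in 1:4)
    expect_lte(sum(abs(bg[ch, ]) > 5 * sqrt(mean(bg[ch, ]^2))), 3)
  # spectral power outside the 4-125 Hz device band below 5%
  for (ch in 1:4) {
    spec <- Mod(fft(bg[ch, ]))^2
    f <- (seq_along(spec) - 1) * 250 / length(spec)
    f <- pmin(f, 250 - f)
    out_band <- sum(spec[f < 4 | f > 125]) / sum(spec)
    expect_lt(out_band, 0.05)
  }
  set.seed(12)
  expect_false(identical(generate_background(prof), generate_background(prof)))
})

test_that("ictal epochs show post-onset RMS growth on involved channels only", {
  prof <- test_profile()
  mask <- prof$seizure_params$channel_mask
  set.seed(21)
  gen <- generate_ictal_epoch(prof, onset = 45)
  expect_equal(gen$annotation$t, 45)
  for (ch in 1:4) {
    w <- windowed_rms(gen$samples[ch, ])
    pre <- mean(w[1:44])
    post <- mean(w[50:60])    # past the recruitment ramp
    if (ch %in% mask) expect_gt(post / pre, 2)
    else expect_lt(abs(post / pre - 1), 0.35)
  }
})

test_that("ictal onset boundaries are honored", {
  prof <- test_profile()
  set.seed(22)
  gen0 <- generate_ictal_epoch(prof, onset = 0)
  expect_equal(gen0$annotation$t, 0)
  w <- windowed_rms(gen0$samples[prof$seizure_params$channel_mask[1], ])
  expect_gt(mean(w[10:30]), 2 * prof$background_params$rms_uv)
  expect_error(generate_ictal_epoch(prof, -1), "onset")
  expect_error(generate_ictal_epoch(prof, 90), "onset")
  expect_error(generate_ictal_epoch(prof, 85), "no room")
})

test_that("confound classes meet their defining contracts", {
  prof <- test_profile()
  set.seed(31)

  brief <- generate_confound_epoch(prof, "brief_ictal")
  expect_equal(brief$annotation$s, 1L)
  expect_lte(brief$duration, 10)

  single <- generate_confound_epoch(prof, "single_channel_ictal")
  t0 <- single$annotation$t
  elevated <- vapply(1:4, function(ch) {
    w <- windowed_rms(single$samples[ch, ])
    mean(w[min(89, ceiling(t0) + 5):min(89, ceiling(t0) + 15)]) /
      mean(w[1:floor(t0)]) > 2
  }, logical(1))
  expect_equal(sum(elevated), 1L)

  dec <- generate_confound_epoch(prof, "electrodecrement_onset")
  expect_equal(dec$annotation$s, 1L)
  t0 <- dec$annotation$t
  w <- windowed_rms(dec$samples[1, ])
  expect_lt(mean(w[(floor(t0) + 1):(floor(t0) + 2)]), 0.5 * mean(w[1:floor(t0)]))

  dense <- generate_confound_epoch(prof, "dense_interictal")
  expect_equal(dense$annotation$s, 0L)
  # many high-amplitude transient samples despite the non-ictal label,
  # far beyond what a spike-free background shows
  rms <- prof$background_params$rms_uv
  n_dense <- sum(abs(dense$samples) > 3.5 * rms)
  quiet <- generate_background(prof, spike_rate = 0)
  n_quiet <- sum(abs(quiet) > 3.5 * rms)
  expect_gt(n_dense, 300)
  expect_lt(n_quiet, 100)
  expect_gt(n_dense, 3 * n_quiet)

  aro <- generate_confound_epoch(prof, "arousal_transition")
  expect_equal(aro$annotation$s, 0L)

  expect_error(generate_confound_epoch(prof, "nope"), "unknown confound")
})

test_that("cohort generation is reproducible with the configured composition", {
  cfg <- cohort_config(n_patients = 2, epochs_per_patient = 10,
                       ictal_fraction = 0.4, master_seed = 31)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$annotations), 20)
  expect_equal(sum(co$annotations$s), 8)          # 2 x round(10 * 0.4)
  # strictly increasing timestamps per patient
  for (p in unique(co$annotations$patient_id)) {
    ts <- vapply(co$epochs[co$annotations$epoch_id[
      co$annotations$patient_id == p]],
      function(e) as.numeric(e$recorded_at), numeric(1))
    expect_false(is.unsorted(ts, strictly = TRUE))
  }
  co2 <- generate_cohort(cfg)
  expect_identical(co$annotations, co2$annotations)
  expect_identical(co$epochs[[5]]$samples, co2$epochs[[5]]$samples)
})

test_that("written cohorts are byte-identical across runs and load back", {
  cfg <- cohort_config(n_patients = 2, epochs_per_patient = 4,
                       ictal_fraction = 0.5, master_seed = 9)
  d1 <- file.path(withr::local_tempdir(), "c1")
  d2 <- file.path(withr::local_tempdir(), "c2")
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  back <- load_cohort(d1)
  expect_equal(back$annotations$s, generate_cohort(cfg)$annotations$s)
  expect_identical(back$epochs[[1]]$samples,
                   generate_cohort(cfg)$epochs[[1]]$samples)
})

test_that("every generated annotation is consistent with its signal", {
  co <- small_cohort()
  ann <- co$annotations
  for (i in sample(which(ann$s == 1), 5)) {
    row <- ann[i, ]
    prof <- co$profiles[[row$patient_id]]
    mask <- prof$seizure_params$channel_mask
    x <- co$epochs[[row$epoch_id]]$samples
    t0 <- row$t_seconds
    w <- windowed_rms(x[mask[1], ])
    post_win <- min(89, ceiling(t0) + 5):min(89, ceiling(t0) + 12)
    if (t0 >= 5)
      expect_gt(mean(w[post_win]) / mean(w[1:floor(t0)]), 1.8)
  }
  for (i in sample(which(ann$s == 0), 5)) {
    row <- ann[i, ]
    x <- co$epochs[[row$epoch_id]]$samples
    w <- windowed_rms(x[1, ])
    expect_lt(max(w) / median(w), 4)    # no sustained discharge
  }
})

test_that("summarize_cohort reproduces the published cohort summary", {
  tab <- load_cohort_table()
  sm <- summarize_cohort(tab)
  expect_equal(sm$total_ictal_patterns, 5226)
  expect_equal(sm$total_ieeg_files, 18368)
  expect_equal(sm$total_recording_days, 7346)
  expect_equal(sm$mean_age, 33.9)
  expect_equal(sm$n_female, 13)
  expect_equal(sm$mean_weeks_recording, 47.7)
  one <- summarize_cohort(tab[5, ])
  expect_equal(one$total_ictal_patterns, tab$n_ictal_patterns[5])
  expect_equal(one$n_patients, 1)
  expect_error(summarize_cohort(tab[0, ]), "non-empty")
})
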