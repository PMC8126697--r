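test_that("quantize_adc maps onto the 10-bit grid, clips, and is idempotent", {
  # a fine ramp across (and beyond) the range must hit all 1024 levels
  ramp <- seq(-600, 600, by = 0.1)
  q <- quantize_adc(ramp)
  expect_equal(length(unique(q)), 1024)
  expect_equal(max(q), 512)
  expect_equal(min(q), -512)

  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(500, sd = runif(1, 1, 400))
    q1 <- quantize_adc(x)
    expect_identical(quantize_adc(q1), q1)             # idempotent
    expect_lte(max(abs(q1 - pmax(pmin(x, 512), -512))),
               1024 / 1023 / 2 + 1e-9)                 # nearest level
    xs <- sort(x)
    expect_false(is.unsorted(quantize_adc(xs)))        # monotone
  }
})

test_that("quantize_adc rejects non-finite samples with a located message", {
  m <- matrix(0, 4, 10)
  m[3, 7] <- NaN
  expect_error(quantize_adc(m), "channel 3.*index 7")
  expect_error(quantize_adc(c(1, Inf)), "index 2")
})

test_that("epoch and annotation constructors enforce the RNS conventions", {
  expect_error(ieeg_epoch(matrix(0, 3, 22500), "p", Sys.time()),
               "channel count")
  expect_error(ieeg_epoch(matrix(0, 4, 1000), "p", Sys.time()),
               "samples per channel")
  expect_error(ieeg_epoch(matrix(0, 4, 22500), "p", Sys.time(),
                          sampling_rate = 200), "sampling_rate")
  expect_error(onset_annotation(2), "0 or 1")
  expect_error(onset_annotation(1, 95), "\\[0, 90\\)")
  expect_error(onset_annotation(1, NA), "required")
  expect_identical(onset_annotation(0, 12)$t, NA_real_)
})

test_that("EDF round trip preserves quantized samples exactly", {
  ep <- test_epoch(seed = 3)
  ann <- onset_annotation(1, 41.237)
  path <- file.path(withr::local_tempdir(), "e1.edf")
  write_epoch(ep, ann, path)
  back <- read_epoch(path)
  expect_identical(back$epoch$samples, ep$samples)   # bit-exact
  expect_equal(back$annotation$s, 1L)
  expect_equal(back$annotation$t, 41.237)
  expect_equal(back$epoch$patient_id, "P01")
  expect_equal(back$epoch$trigger, "scheduled")
  expect_equal(back$epoch$sampling_rate, 250L)
  # header carries the sampling frequency: 22,500 samples / 90 s record
  hdr <- ictalnet:::read_edf(path)
  expect_equal(hdr$fs, 250)
  expect_equal(hdr$dims, rep("uV", 4))
})

test_that("non-ictal sidecar stores an empty onset, not 0", {
  ep <- test_epoch(seed = 4)
  path <- file.path(withr::local_tempdir(), "e0.edf")
  write_epoch(ep, onset_annotation(0), path)
  row <- read.csv(sub("edf$", "csv", path))
  expect_true(is.na(row$t_seconds))
  expect_identical(read_epoch(path)$annotation$t, NA_real_)
})

test_that("read_epoch rejects malformed inputs naming the field", {
  dir <- withr::local_tempdir()
  # 3-channel EDF
  p3 <- file.path(dir, "bad3.edf")
  ictalnet:::write_edf(p3, matrix(0, 3, 22500), 250, paste0("c", 1:3),
                       -512, 512, 0, 1023,
                       as.POSIXct("2021-01-01", tz = "UTC"), "x", "y")
  expect_error(read_epoch(p3), "channel count")
  # onset out of bounds in the sidecar
  ok <- file.path(dir, "ok.edf")
  write_epoch(test_epoch(), onset_annotation(1, 10), ok)
  side <- read.csv(sub("edf$", "csv", ok))
  side$t_seconds <- 95
  write.csv(side, sub("edf$", "csv", ok), row.names = FALSE)
  expect_error(read_epoch(ok), "\\[0, 90\\)")
  expect_error(read_epoch(file.path(dir, "missing.edf")), "no such file")
})

test_that("load_cohort_table reads the packaged 22-patient fixture", {
  tab <- load_cohort_table()
  expect_equal(nrow(tab), 22)
  expect_equal(tab$n_ictal_patterns[tab$patient == 16], 2057)
  expect_equal(tab$n_days[tab$patient == 16], 732)
  expect_equal(tab$n_ieeg_files[tab$patient == 16], 4110)
  expect_true(all(tab$n_ictal_patterns <= tab$n_ieeg_files))
})

test_that("load_cohort_table flags schema problems", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.csv")
  writeLines("patient,age", empty)
  expect_error(load_cohort_table(empty), "schema error")
  miss <- file.path(dir, "miss.csv")
  writeLines(c("patient,age,gender", "1,30,F"), miss)
  expect_error(load_cohort_table(miss), "missing column")
})
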