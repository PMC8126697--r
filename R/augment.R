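#' Training-time augmentation configuration
#'
#' Label-preserving transformations applied to training examples only:
#' zero-padding with a uniformly random 90-s crop, and a per-epoch
#' amplitude rescale. Evaluation always runs on untransformed epochs.
#'
#' @param pad_seconds zero padding added before and after the epoch (s).
#' @param crop_seconds crop length (s); fixed at the epoch duration.
#' @param scale_min,scale_max amplitude rescale range (one factor per
#'   epoch, shared by all 4 channels).
#' @param enabled master switch; when `FALSE`, [augment_example()] is the
#'   identity.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(pad_seconds = 30, crop_seconds = 90,
                           scale_min = 0.8, scale_max = 1.2,
                           enabled = TRUE) {
  stopifnot(pad_seconds >= 0, crop_seconds == IEEG_DURATION,
            scale_min <= scale_max)
  structure(list(pad_seconds = pad_seconds, crop_seconds = crop_seconds,
                 scale_min = scale_min, scale_max = scale_max,
                 enabled = isTRUE(enabled)),
            class = "augment_config")
}

#' Pad with zeros and take a random 90-s crop
#'
#' Conceptually pads `pad_seconds` of zero voltage before and after the
#' epoch and selects a crop start `c` uniformly over the padded slack (an
#' integer sample offset). The onset of an ictal epoch shifts to
#' `t' = t + pad_seconds - c`; crops that would move the onset out of
#' `[0, 90)` are rejection-resampled (at most `max_tries`, then the
#' centered crop, i.e. the identity placement, is used) so the transform
#' stays label-preserving. The output always has exactly 22,500 samples.
#'
#' @param samples 4 x 22,500 numeric matrix.
#' @param s binary ictal label.
#' @param t onset (s) when `s = 1`, else `NA`.
#' @param cfg an [augment_config()].
#' @param max_tries rejection-resampling bound.
#' @return `list(samples, s, t, crop_start)` with `crop_start` the chosen
#'   offset in samples.
#' @export
pad_and_crop <- function(samples, s, t = NA_real_, cfg = augment_config(),
                         max_tries = 100L) {
  stopifnot(is.matrix(samples), ncol(samples) == IEEG_SAMPLES)
  pad_n <- round(cfg$pad_seconds * IEEG_FS)
  draw <- function() sample.int(2L * pad_n + 1L, 1L) - 1L
  crop <- draw()
  if (s == 1) {
    shift_t <- function(cc) t + cfg$pad_seconds - cc / IEEG_FS
    tries <- 0L
    while ((shift_t(crop) < 0 || shift_t(crop) >= IEEG_DURATION) &&
           tries < max_tries) {
      crop <- draw()
      tries <- tries + 1L
    }
    if (shift_t(crop) < 0 || shift_t(crop) >= IEEG_DURATION) crop <- pad_n
    t_new <- shift_t(crop)
  } else {
    t_new <- NA_real_
  }
  out <- matrix(0, nrow(samples), IEEG_SAMPLES)
  # padded index range covered by the crop, mapped back to the original
  src_lo <- max(1L, crop - pad_n + 1L)
  src_hi <- min(IEEG_SAMPLES, crop - pad_n + IEEG_SAMPLES)
  if (src_lo <= src_hi) {
    dst_lo <- src_lo - (crop - pad_n)
    out[, dst_lo:(dst_lo + src_hi - src_lo)] <-
      samples[, src_lo:src_hi, drop = FALSE]
  }
  list(samples = out, s = s, t = t_new, crop_start = crop)
}

#' Rescale epoch amplitude by one uniform factor
#'
#' Draws `f ~ Uniform(scale_min, scale_max)` once per epoch and multiplies
#' all 4 channels by it; the annotation is unchanged.
#'
#' @inheritParams pad_and_crop
#' @return `list(samples, factor)`.
#' @export
amplitude_rescale <- function(samples, cfg = augment_config()) {
  f <- runif(1, cfg$scale_min, cfg$scale_max)
  list(samples = samples * f, factor = f)
}

#' Apply the full training augmentation to one example
#'
#' Composition of [pad_and_crop()] and [amplitude_rescale()]; the ictal
#' label never changes and an onset, if present, stays inside `[0, 90)`.
#' With `cfg$enabled = FALSE` the example is returned untouched (the
#' evaluation path).
#'
#' @param example `list(samples, s, t, patient_index)`.
#' @param cfg an [augment_config()].
#' @return an example of the same shape.
#' @export
augment_example <- function(example, cfg = augment_config()) {
  if (!cfg$enabled) return(example)
  pc <- pad_and_crop(example$samples, example$s, example$t, cfg)
  rs <- amplitude_rescale(pc$samples, cfg)
  example$samples <- rs$samples
  example$t <- pc$t
  example
}
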