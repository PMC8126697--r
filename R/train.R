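#' Binary cross-entropy (natural log)
#'
#' `-s log(s_hat) - (1 - s) log(1 - s_hat)`, with `s_hat` clamped to
#' `[eps, 1 - eps]` for numerical safety. Vectorized.
#'
#' @param s binary label(s) in `{0, 1}`.
#' @param s_hat predicted probability(ies) in (0, 1).
#' @param eps clamp width.
#' @return non-negative value(s) in nats.
#' @export
crossentropy <- function(s, s_hat, eps = 1e-7) {
  if (!all(s %in% c(0, 1))) stop_fmt("labels s must be 0 or 1")
  p <- pmin(pmax(s_hat, eps), 1 - eps)
  -s * log(p) - (1 - s) * log(1 - p)
}

#' Huber loss with a 1-second branch point
#'
#' Quadratic, `(t - t_hat)^2 / 2`, for `|t - t_hat| <= 1`; linear,
#' `|t - t_hat| - 1/2`, beyond. Both branches meet (value 1/2, slope 1)
#' at the threshold, making the loss continuous and once-differentiable.
#' Units are seconds throughout. Vectorized.
#'
#' @param t true onset(s), seconds.
#' @param t_hat predicted onset(s), seconds.
#' @param delta branch point (default 1 s).
#' @return non-negative value(s).
#' @export
huber <- function(t, t_hat, delta = 1) {
  stopifnot(all(is.finite(t)), all(is.finite(t_hat)))
  d <- abs(t - t_hat)
  ifelse(d <= delta, 0.5 * d^2, delta * (d - 0.5 * delta))
}

#' Joint detection + onset-regression loss for one example
#'
#' `total = crossentropy(s, s_hat) + weight * huber(t, t_hat)`. For a
#' non-ictal example (`s = 0`) the onset is undefined and the Huber term
#' is masked to zero, so no regression target has to be fabricated.
#'
#' @param s binary ictal label.
#' @param s_hat predicted probability.
#' @param t,t_hat onset and estimate (seconds); ignored when `s = 0`.
#' @param weight Huber coefficient (default 0.1).
#' @return list of class `loss_breakdown` with components `ce`, `hub`,
#'   `total` (`total == ce + weight * hub` exactly).
#' @export
hybrid_loss <- function(s, s_hat, t = NA_real_, t_hat = NA_real_,
                        weight = 0.1) {
  ce <- crossentropy(s, s_hat)
  hub <- if (s == 1) huber(t, t_hat) else 0
  structure(list(ce = ce, hub = hub, total = ce + weight * hub),
            class = "loss_breakdown")
}

#' Training configuration
#'
#' Plain SGD, 20 epochs, batch 128, cyclical learning rate falling
#' linearly from 0.1 to 0.025 within each 4-epoch cycle and held at
#' 0.025 for the final two epochs. Momentum and weight decay are exposed
#' but default to 0.
#'
#' @param n_epochs,batch_size,lr_high,lr_low,cycle_epochs,final_const_epochs
#'   schedule parameters.
#' @param huber_weight coefficient of the Huber term.
#' @param momentum,weight_decay optional SGD extras (default 0).
#' @param seed integer seed controlling shuffling, augmentation and
#'   dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(n_epochs = 20L, batch_size = 128L, lr_high = 0.1,
                         lr_low = 0.025, cycle_epochs = 4L,
                         final_const_epochs = 2L, huber_weight = 0.1,
                         momentum = 0, weight_decay = 0, seed = 1L) {
  stopifnot(lr_low <= lr_high, final_const_epochs <= n_epochs,
            cycle_epochs >= 1, batch_size >= 1, n_epochs >= 1)
  structure(list(n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size),
                 lr_high = lr_high, lr_low = lr_low,
                 cycle_epochs = as.integer(cycle_epochs),
                 final_const_epochs = as.integer(final_const_epochs),
                 huber_weight = huber_weight, momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Cyclical learning rate
#'
#' Within each `cycle_epochs`-long cycle the rate decays linearly from
#' `lr_high` at the cycle start to `lr_low` at the cycle end, then
#' resets; the final `final_const_epochs` epochs return `lr_low` exactly.
#'
#' @param epoch_index 0-based epoch index, `0 <= epoch_index < n_epochs`.
#' @param config a [train_config()].
#' @return the learning rate for that epoch.
#' @export
cyclical_lr <- function(epoch_index, config = train_config()) {
  if (any(epoch_index < 0 | epoch_index >= config$n_epochs))
    stop_fmt("epoch_index out of range [0, %d)", config$n_epochs)
  pos <- epoch_index %% config$cycle_epochs
  lr <- if (config$cycle_epochs == 1L) config$lr_high
        else config$lr_high - (config$lr_high - config$lr_low) * pos /
             (config$cycle_epochs - 1L)
  ifelse(epoch_index >= config$n_epochs - config$final_const_epochs,
         config$lr_low, lr)
}

## recursive SGD step over the nested parameter list; velocity has the
## same shape as par and is only used when momentum > 0
sgd_step <- function(par, grads, velocity, lr, momentum, weight_decay) {
  if (is.list(par)) {
    for (nm in names(par)) {
      if (is.null(grads[[nm]])) next
      res <- sgd_step(par[[nm]], grads[[nm]], velocity[[nm]], lr,
                      momentum, weight_decay)
      par[[nm]] <- res$par
      velocity[[nm]] <- res$vel
    }
    return(list(par = par, vel = velocity))
  }
  g <- grads + weight_decay * par
  v <- momentum * velocity + g
  list(par = par - lr * v, vel = v)
}

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

## assemble a batch of examples into the engine's inputs
batch_tensors <- function(examples, n_patients) {
  B <- length(examples)
  X <- array(0, c(IEEG_CHANNELS, IEEG_SAMPLES, B))
  s <- numeric(B); t <- numeric(B); tmask <- numeric(B); pidx <- integer(B)
  for (i in seq_len(B)) {
    ex <- examples[[i]]
    X[, , i] <- ex$samples
    s[i] <- ex$s
    tmask[i] <- as.numeric(ex$s == 1 && is.finite(ex$t))
    t[i] <- if (tmask[i] == 1) ex$t else 0
    pidx[i] <- ex$patient_index
  }
  list(X = X, onehot = onehot_matrix(pidx, n_patients), s = s, t = t,
       tmask = tmask)
}

#' Train the detector by mini-batch SGD
#'
#' Augmentation (when enabled) is applied on the fly to each training
#' example; the batch loss is the mean hybrid loss. Fully seeded: the
#' same configuration and seed reproduce the same history.
#'
#' @param network an [build_network()] object.
#' @param train_set list of examples
#'   `list(samples = 4 x 22500 matrix, s, t, patient_index)`.
#' @param config a [train_config()].
#' @param augment_cfg an [augment_config()]; pass
#'   `augment_config(enabled = FALSE)` to train on raw epochs.
#' @param verbose print per-epoch losses.
#' @return the trained network, with a `history` data.frame
#'   (`epoch, lr, loss_total, loss_ce, loss_huber`) attached.
#' @export
train_network <- function(network, train_set, config = train_config(),
                          augment_cfg = augment_config(),
                          verbose = FALSE) {
  stopifnot(inherits(network, "ictal_net"))
  if (length(train_set) == 0L) stop_fmt("empty training set")
  np <- network$spec$n_patients
  for (ex in train_set) {
    if (ex$patient_index < 1 || ex$patient_index > np)
      stop_fmt("example patient_index %d outside 1..%d",
               ex$patient_index, np)
  }
  set.seed(config$seed)
  par <- network$par
  state <- network$state
  velocity <- if (config$momentum > 0) zeros_like(par) else zeros_like(par)
  n <- length(train_set)
  history <- data.frame()
  for (epoch in 0:(config$n_epochs - 1L)) {
    lr <- cyclical_lr(epoch, config)
    idx <- sample.int(n)
    tot <- ce <- hub <- 0
    seen <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      take <- idx[start:min(start + config$batch_size - 1L, n)]
      examples <- lapply(train_set[take], augment_example, cfg = augment_cfg)
      bt <- batch_tensors(examples, np)
      bseed <- sample.int(2147483646L, 1L)
      res <- cpp_net_run(par, state, network$arch, bt$X, bt$onehot, TRUE,
                         network$spec$dropout_rate, bseed,
                         bt$s, bt$t, bt$tmask, config$huber_weight)
      upd <- sgd_step(par, res$grads, velocity, lr, config$momentum,
                      config$weight_decay)
      par <- upd$par
      velocity <- upd$vel
      state <- res$state
      b <- length(take)
      tot <- tot + res$loss_total * b
      ce <- ce + res$loss_ce * b
      hub <- hub + res$loss_huber * b
      seen <- seen + b
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, loss_total = tot / seen,
      loss_ce = ce / seen, loss_huber = hub / seen))
    if (verbose)
      message(sprintf("epoch %2d lr %.3f loss %.4f (ce %.4f hub %.3f)",
                      epoch, lr, tot / seen, ce / seen, hub / seen))
  }
  network$par <- par
  network$state <- state
  network$history <- history
  network
}

#' Turn a cohort into a list of training examples
#'
#' @param cohort an `ieeg_cohort`.
#' @param patient_levels character vector fixing the patient -> one-hot
#'   index mapping; defaults to the cohort's patients in order.
#' @param epoch_ids optional subset of epoch ids.
#' @return list of examples as consumed by [train_network()].
#' @export
cohort_examples <- function(cohort, patient_levels = NULL,
                            epoch_ids = NULL) {
  ann <- cohort$annotations
  if (!is.null(epoch_ids)) ann <- ann[ann$epoch_id %in% epoch_ids, ]
  patient_levels <- patient_levels %||% unique(cohort$annotations$patient_id)
  lapply(seq_len(nrow(ann)), function(i) {
    row <- ann[i, ]
    list(samples = cohort$epochs[[row$epoch_id]]$samples,
         s = row$s,
         t = if (row$s == 1) row$t_seconds else NA_real_,
         patient_index = match(row$patient_id, patient_levels),
         epoch_id = row$epoch_id)
  })
}
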