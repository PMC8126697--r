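#' Linear filter schedule for the residual stack
#'
#' Filter counts grow linearly from `f_first` in the first block to
#' `f_penultimate` in the penultimate block (rounded to the nearest
#' integer); the final block keeps `f_penultimate` as its convolution
#' width, its input being widened by the one-hot patient code instead.
#'
#' @param n_blocks number of residual blocks (>= 2).
#' @param f_first filters in the first layer/block.
#' @param f_penultimate filters at the penultimate block.
#' @return integer vector of length `n_blocks`.
#' @export
filter_schedule <- function(n_blocks, f_first, f_penultimate) {
  if (!(n_blocks >= 2) || f_first < 1 || f_penultimate < f_first)
    stop_fmt("need n_blocks >= 2 and f_penultimate >= f_first >= 1")
  if (n_blocks == 2) return(as.integer(c(f_first, f_penultimate)))
  k <- seq_len(n_blocks - 1)
  sched <- round(f_first + (f_penultimate - f_first) * (k - 1) /
                   (n_blocks - 2))
  as.integer(c(sched, f_penultimate))
}

#' Structural description of the detector network
#'
#' A pre-activation residual 1-D CNN: an initial stride-2 convolution,
#' `n_blocks` residual blocks of two convolutions each (kernel
#' `kernel_size`), stride 2 at the start of every other block (blocks
#' 2, 4, ...), batch normalization + ReLU before every convolution,
#' kernel-1 projection shortcuts wherever shape changes. Between the
#' penultimate and final block the one-hot patient code is tiled along
#' time and concatenated on the channel axis. The head global-average
#' pools over time and emits a sigmoid ictal probability and a linear
#' onset-time estimate (seconds).
#'
#' @param n_patients width of the one-hot patient code (>= 1).
#' @param n_blocks residual blocks (default 11, for 23 main-path
#'   convolutional layers).
#' @param kernel_size convolution kernel (default 16).
#' @param first_filters,penultimate_filters endpoints of the linear
#'   filter schedule (defaults 16 and 116).
#' @param dropout_rate dropout after the second activation in each block
#'   (0 disables).
#' @param bn_momentum running-statistics update rate for batch norm.
#' @return an object of class `ictal_net_spec`.
#' @export
network_spec <- function(n_patients, n_blocks = 11L, kernel_size = 16L,
                         first_filters = 16L, penultimate_filters = 116L,
                         dropout_rate = 0.2, bn_momentum = 0.1) {
  if (n_patients < 1) stop_fmt("n_patients must be >= 1")
  filters <- if (n_blocks == 1L) penultimate_filters
             else filter_schedule(n_blocks, first_filters,
                                  penultimate_filters)
  strides <- ifelse(seq_len(n_blocks) %% 2 == 0, 2L, 1L)
  structure(list(
    n_blocks = as.integer(n_blocks),
    convs_per_block = 2L,
    kernel_size = as.integer(kernel_size),
    first_filters = as.integer(first_filters),
    penultimate_filters = as.integer(penultimate_filters),
    per_block_filters = filters,
    block_strides = strides,
    stride2_blocks = which(strides == 2L),
    n_patients = as.integer(n_patients),
    dropout_rate = dropout_rate,
    bn_momentum = bn_momentum,
    input_channels = IEEG_CHANNELS), class = "ictal_net_spec")
}

he_init <- function(n_out, fan_in) {
  matrix(rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), n_out, fan_in)
}

bn_par <- function(c) list(g = rep(1, c), b = rep(0, c))
bn_state <- function(c) list(m = rep(0, c), v = rep(1, c))
conv_par <- function(c_out, c_in, k) {
  list(W = he_init(c_out, c_in * k), b = rep(0, c_out))
}

#' Build (initialize) the detector network
#'
#' He-initialized weights; batch-norm scale 1 / shift 0; the onset head
#' bias starts at the epoch midpoint (45 s) as an uninformed prior.
#'
#' @param spec an [network_spec()].
#' @param seed optional integer seed for the weight draw.
#' @return an object of class `ictal_net`: `spec`, trainable `par`,
#'   batch-norm running `state`, and the `arch` descriptor consumed by
#'   the compute engine.
#' @export
build_network <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ictal_net_spec"))
  if (!is.null(seed)) set.seed(seed)
  nb <- spec$n_blocks
  k <- spec$kernel_size
  f <- spec$per_block_filters
  # input channels of every block's first conv (one-hot widens the last)
  cin <- c(f[1], f[-nb])
  cin[nb] <- cin[nb] + spec$n_patients
  par <- list(
    bn_in = bn_par(spec$input_channels),
    conv0 = conv_par(f[1], spec$input_channels, k),
    blocks = vector("list", nb),
    bn_fin = bn_par(f[nb]),
    head = NULL)
  state <- list(bn_in = bn_state(spec$input_channels),
                blocks = vector("list", nb),
                bn_fin = bn_state(f[nb]))
  for (i in seq_len(nb)) {
    s <- spec$block_strides[i]
    bl <- list(bn1 = bn_par(cin[i]),
               conv1 = conv_par(f[i], cin[i], k),
               bn2 = bn_par(f[i]),
               conv2 = conv_par(f[i], f[i], k))
    if (s != 1L || cin[i] != f[i])
      bl$proj <- conv_par(f[i], cin[i], 1L)
    par$blocks[[i]] <- bl
    state$blocks[[i]] <- list(bn1 = bn_state(cin[i]),
                              bn2 = bn_state(f[i]))
  }
  # Onset-head bias starts at the nominal pre-trigger depth of
  # detection-triggered RNS clips (30 s) — the prior onset position.
  # With the Huber term's 0.1 weight the head drifts slowly under SGD,
  # so an uninformed init would dominate the error budget.
  par$head <- list(Ws = rnorm(f[nb], sd = sqrt(2 / f[nb])), bs = 0,
                   Wt = rnorm(f[nb], sd = sqrt(2 / f[nb])),
                   bt = 30)
  arch <- list(stride0 = 2L,
               block_strides = spec$block_strides,
               block_cin = as.integer(cin),
               n_patients = spec$n_patients,
               bn_momentum = spec$bn_momentum)
  structure(list(spec = spec, par = par, state = state, arch = arch),
            class = "ictal_net")
}

#' Structural summary by traversal
#'
#' Counts are computed by walking the parameter tree, not read back from
#' the spec, so construction bugs surface in tests.
#'
#' @param network an [build_network()] object.
#' @return list with main-path convolution count, residual block count,
#'   projection-shortcut count, trainable parameter count and the overall
#'   temporal downsampling factor.
#' @export
structural_summary <- function(network) {
  stopifnot(inherits(network, "ictal_net"))
  par <- network$par
  n_blocks <- length(par$blocks)
  n_conv_main <- 1L +
    sum(vapply(par$blocks, function(b)
      sum(c("conv1", "conv2") %in% names(b)), integer(1)))
  n_proj <- sum(vapply(par$blocks, function(b)
    "proj" %in% names(b), logical(1)))
  count <- function(x) {
    if (is.list(x)) sum(vapply(x, count, numeric(1))) else length(x)
  }
  downsample <- network$arch$stride0 * prod(network$arch$block_strides)
  list(n_conv_main = n_conv_main,
       n_residual_blocks = n_blocks,
       n_projection_shortcuts = n_proj,
       n_parameters = count(par),
       downsampling_factor = downsample)
}

onehot_matrix <- function(patient_indices, n_patients) {
  oh <- matrix(0, n_patients, length(patient_indices))
  bad <- patient_indices < 1 | patient_indices > n_patients
  if (any(bad))
    stop_fmt("patient_index out of range 1..%d", n_patients)
  oh[cbind(patient_indices, seq_along(patient_indices))] <- 1
  oh
}

#' Batch inference
#'
#' Deterministic: batch norm uses running statistics and dropout is off,
#' so the batched forward equals the per-item forward.
#'
#' @param network an `ictal_net`.
#' @param x numeric array `4 x 22500 x N` (or a matrix for `N = 1`).
#' @param patient_indices integer vector (1-based), length `N`.
#' @return `data.frame(s_hat, t_hat)`.
#' @export
net_predict <- function(network, x, patient_indices) {
  stopifnot(inherits(network, "ictal_net"))
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) != 3L || dim(x)[1] != IEEG_CHANNELS ||
      dim(x)[2] != IEEG_SAMPLES)
    stop_fmt("input must be %d x %d x N", IEEG_CHANNELS, IEEG_SAMPLES)
  if (dim(x)[3] != length(patient_indices))
    stop_fmt("need one patient index per batch item")
  oh <- onehot_matrix(patient_indices, network$spec$n_patients)
  res <- cpp_net_run(network$par, network$state, network$arch,
                     x, oh, FALSE, 0, 0L,
                     numeric(0), numeric(0), numeric(0), 0.1)
  data.frame(s_hat = res$s_hat, t_hat = res$t_hat)
}

#' Run the detector on one epoch
#'
#' @param network an `ictal_net`.
#' @param epoch an [ieeg_epoch()] (or a bare 4 x 22,500 matrix).
#' @param patient_index 1-based index into the network's one-hot code.
#' @return `list(s_hat, t_hat)`: ictal probability in (0, 1) and onset
#'   estimate in seconds.
#' @export
net_forward <- function(network, epoch, patient_index) {
  samples <- if (inherits(epoch, "ieeg_epoch")) epoch$samples else epoch
  out <- net_predict(network, samples, patient_index)
  list(s_hat = out$s_hat[1], t_hat = out$t_hat[1])
}
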