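`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible 31-bit seed from a master seed and a tag
#'
#' A single master seed fans out to per-module seeds by hashing the tag
#' string, so that e.g. cohort generation and training draw from
#' independent, reproducible streams.
#'
#' @param master_seed integer master seed.
#' @param tag character tag naming the consumer.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, tag) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483629
  as.integer((abs(master_seed) %% 2147483629 * 7919 + h) %% 2147483627 + 1)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
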