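# Named PRNG streams. One user-facing seed fans out to independent streams
# (fixtures, weight init, training, evaluation, generation ...) so that, e.g.,
# changing the evaluation cadence never perturbs the training trajectory.

# deterministic 31-bit hash of a string (polynomial rolling hash)
.str_hash31 <- function(s) {
  h <- 17
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

#' Create a named PRNG substream
#'
#' @param seed integer master seed.
#' @param name stream name (e.g. "training", "eval").
#' @return an opaque stream object for [with_rng()].
#' @keywords internal
rng_stream <- function(seed, name) {
  sub <- (as.numeric(seed) * 48271 + .str_hash31(name)) %% 2147483647
  e <- new.env(parent = emptyenv())
  e$seed0 <- as.integer(sub)
  e$state <- NULL
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' The stream's state advances; the global RNG state is left untouched.
#' @keywords internal
with_rng <- function(stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed0, kind = "Mersenne-Twister")
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  res <- expr
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}
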