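#' Independent, seedable random-number streams
#'
#' Each stream owns a private copy of R's Mersenne-Twister state, so replicas
#' and the swap scheduler draw from independent, reproducible sequences
#' regardless of execution order. Drawing from a stream never disturbs the
#' global RNG state.
#'
#' @param seed integer seed for the stream
#' @return an object of class `rng_stream`
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  e$seed <- as.integer(seed)
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param stream an [rng_stream()]
#' @param expr expression drawing random numbers
#' @return the value of `expr`; the stream's state advances, the global RNG
#'   state is restored
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Fan a master seed out into child stream seeds
#'
#' Deterministic splitting keeps per-replica streams reproducible no matter
#' how many replicas run or in which order. Child seeds stay below 2^31.
#'
#' @param seed master seed
#' @param n number of child seeds
#' @return integer vector of `n` seeds
#' @export
spawn_seeds <- function(seed, n) {
  s <- rng_stream(seed)
  with_stream(s, sample.int(.Machine$integer.max - 1L, n))
}
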