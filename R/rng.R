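#' Derive a named substream seed from a master seed
#'
#' The scenario factorial (A/B share a population realization, A/C share a
#' habitat realization, ...) requires that each stochastic component of the
#' simulator draw from its own reproducible stream. A master seed is expanded
#' into named substreams with a small multiplicative hash; the result is a
#' valid 32-bit integer seed for [set.seed()].
#'
#' Not cryptographic; collisions between unrelated (seed, name) pairs are
#' astronomically unlikely at the scale used here.
#'
#' @param seed master seed (integer).
#' @param stream character stream name, e.g. `"habitat"`.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stream)) {
    h <- (h * 69069 + code) %% m
  }
  # one extra scramble so streams differing in a final character diverge fully
  h <- (h * 48271) %% m
  as.integer(h)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}
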