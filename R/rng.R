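# Seed plumbing: every stochastic entry point takes an optional integer seed.
# A NULL seed uses (and advances) the caller's RNG stream; an explicit seed is
# applied locally and the caller's stream is restored afterwards, so seeded
# calls are pure functions of their arguments.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed from a master seed
#'
#' Deterministically mixes a master seed with one or more integer indices
#' (e.g. grid-cell row, trial block) so that independent substreams can be
#' re-created in isolation: re-running a single sweep cell with its derived
#' seed reproduces the values it had inside the full sweep.
#'
#' @param seed master seed (single integer).
#' @param ... further non-negative integer indices identifying the substream.
#' @return a single integer in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' mix_seed(1, 3, 7)
#' @export
mix_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  stopifnot(all(is.finite(idx)))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 104729
  for (k in as.numeric(idx)) {
    # multiplier kept small enough that h * mult + k stays exact in doubles
    h <- (h * 48271 + (k %% m) + 1) %% m
  }
  as.integer(h + 1)
}
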