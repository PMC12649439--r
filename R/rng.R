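# Seed plumbing. Every stochastic operation in the package takes an explicit
# integer seed; nested operations derive independent substream seeds from it
# so that, e.g., repetition 3 of gesture 2 for user 5 is reproducible on its
# own, independent of how many other repetitions were generated.

#' Derive a substream seed from a parent seed
#'
#' Deterministically mixes a parent seed with one or more integer stream
#' labels (for example a user index, gesture index and repetition index) into
#' a new seed in `[1, 2^31 - 2]`. Used throughout the package to give every
#' user/gesture/repetition its own independent random substream.
#'
#' @param seed Parent integer seed.
#' @param ... Integer stream labels, mixed in order.
#' @return An integer seed.
#' @examples
#' derive_seed(42, 1, 3)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps products exact in double precision
  s <- abs(as.numeric(seed)) %% m
  for (w in c(...)) {
    s <- (s * 69069 + abs(as.numeric(w)) + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
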