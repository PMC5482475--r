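#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Study pipelines use many independent random streams (the true network,
#' one dataset per replication, cross-validation folds, ...). Deriving each
#' stream's seed deterministically from \code{(seed, label)} makes every
#' component individually reproducible: rerunning one replication does not
#' require replaying the whole study. The derivation is a small 32-bit
#' multiplicative hash of the label folded into the seed; the result is
#' always in \code{[1, 2^31 - 2]} and therefore valid for [set.seed()].
#'
#' @param seed Master integer seed.
#' @param label Character string naming the stream (e.g. \code{"rep3/data"}).
#' @return A single integer seed.
#' @examples
#' seed_stream(1, "truth") != seed_stream(1, "rep1/data")
#' @export
seed_stream <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m + m) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# Evaluates `expr` under `seed` and restores the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))
  expr
}
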