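#' Derive a named RNG substream seed
#'
#' Deterministically maps a master seed plus a character label (and optional
#' integer index) to a new seed in `[1, 2^31 - 2]`. Used so that every
#' stochastic stage of a pipeline run draws from its own reproducible
#' substream: rerunning a single stage in isolation with the same master seed
#' gives the same draws as the full run.
#'
#' @param seed master seed (single integer-valued number).
#' @param label character label naming the substream.
#' @param index optional non-negative integer distinguishing parallel
#'   substreams under the same label (e.g. one per class or repetition).
#' @return a single integer suitable for [set.seed()].
#' @examples
#' substream_seed(42, "base")
#' substream_seed(42, "template", 3)
#' @export
substream_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; all arithmetic stays exact in doubles
  h <- (abs(seed) %% m)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 31 + (index %% m)) %% m
  as.integer(h %% (m - 1) + 1)
}

# Run `expr` under a temporary RNG state seeded from a substream, restoring
# the caller's RNG state afterwards.
with_substream <- function(seed, label, index = 0L, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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
  set.seed(substream_seed(seed, label, index))
  expr
}
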