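#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's random-number
#' state, so seeded package internals never disturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a named substream seed from a root seed; stays below 2^31
substream_seed <- function(seed, stream) {
  offsets <- c(expression = 1L, survival = 2L, mutations = 3L,
               clinical = 4L, genesets = 5L, permutation = 6L)
  if (!stream %in% names(offsets)) stop("unknown substream: ", stream)
  as.integer((as.double(seed) * 16807 + offsets[[stream]]) %% 2147483647)
}
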