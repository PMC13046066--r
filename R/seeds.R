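#' Derive a stage seed from a replicate master seed
#'
#' One master seed per replicate drives every stochastic stage of the
#' pipeline (composition sampling, shuffling, noise injection, data
#' splitting, network initialization, mini-batch ordering) through fixed
#' stream splitting, so that stages are individually reproducible and
#' replicates are independent.
#'
#' @param seed Non-negative integer master seed.
#' @param stage One of `"sampling"`, `"shuffle"`, `"noise"`, `"split"`,
#'   `"init"`, `"batches"`.
#' @param salt Optional extra non-negative integer mixed in when the same
#'   stage runs more than once per replicate (e.g. one noise stream per
#'   dataset variant).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stage, salt = 0L) {
  stages <- c("sampling", "shuffle", "noise", "split", "init", "batches")
  stage <- match.arg(stage, stages)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, is.finite(seed))
  offset <- match(stage, stages)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; arithmetic exact in doubles
  s <- (seed %% m) * 48271 %% m
  s <- (s + offset * 16807) %% m
  s <- (s + (salt %% m) * 69621) %% m
  as.integer(s)
}

# Run expr with the RNG positioned at a derived stage stream when a master
# seed is supplied; with seed = NULL the ambient RNG state is used.
with_stream <- function(seed, stage, salt = 0L, expr) {
  if (!is.null(seed)) set.seed(derive_seed(seed, stage, salt))
  expr
}
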