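# Deterministic seed derivation.
#
# Every stochastic operation in the package takes one integer seed and derives
# per-component / per-replicate / per-variant sub-seeds by counter, so that
# e.g. adding a variant or an individual does not perturb unrelated draws and
# replicate r is reproducible from (seed, r) alone.

#' Derive a deterministic sub-seed from a base seed and counters
#'
#' Mixes a base seed with one or more non-negative integer counters using a
#' multiplicative-congruential hash, returning an integer in `[0, 2^31 - 2]`
#' suitable for [set.seed()]. The same `(seed, ...)` always yields the same
#' sub-seed; distinct counter tuples yield (with overwhelming probability)
#' distinct streams.
#'
#' @param seed Integer base seed.
#' @param ... Non-negative integer counters (e.g. replicate index, component
#'   code, variant index).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(seed, ...) {
  m <- 2147483647                       # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (x in c(...)) {
    h <- (h * 69069 + as.numeric(x) + 1) %% m
  }
  # one extra scramble so (seed) and (seed, 0) differ
  as.integer((h * 69069 + 1) %% m)
}

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
#' afterwards, so localized randomness never perturbs surrounding draws.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
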