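# Reproducible substream seeding.
#
# Datasets must be reproducible independently of iteration order and of how
# many persons or replicates are generated, so every random draw is made
# under a seed derived deterministically from (study seed, replicate index,
# person id, ...) by an integer mixing function, and the global RNG state is
# always restored afterwards.

#' Derive a substream seed from integer keys
#'
#' Deterministic integer hash of any number of integer keys, returning a
#' value in `[0, 2^31 - 1]` suitable for `set.seed()`. Used to give every
#' (replicate, person) pair its own random substream so that generated data
#' do not depend on iteration order, on the total person count, or on which
#' estimators run in between.
#'
#' @param ... Integer keys (study seed, replicate index, person id, ...).
#' @return A single integer seed.
#' @export
mix_seed <- function(...) {
  keys <- c(...)
  stopifnot(length(keys) >= 1, all(is.finite(keys)))
  m <- 2^31
  h <- 104729                                # seed the hash off zero
  for (k in as.numeric(keys)) {
    h <- (h * 69069 + (k %% m) + 1) %% m     # LCG-style mix; exact in doubles
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous `.Random.seed` (or removes it if none existed), so that seeded
#' internals such as the NCI pseudo-person draw never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
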