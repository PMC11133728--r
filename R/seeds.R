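# Seed plumbing: every stochastic operation takes an integer seed and runs
# under a local RNG state, so a single master seed reproduces a whole run
# without disturbing the caller's RNG.

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded to `seed` and restores the
#' caller's RNG state afterwards.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a new seed in
#' `[1, 2^31 - 2]`, so that pipeline stages get independent but reproducible
#' RNG streams.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1000003
  as.integer((abs(as.double(seed)) %% 65521) * 32749 + h + 1)
}
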