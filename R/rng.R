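# Per-consumer randomness.
#
# All stochastic pieces of a simulation draw from counter-based streams keyed
# by (master seed, stream id, trial counter), so a run is a pure function of
# its seed and removing one consumer (e.g. lesioning an input) cannot shift
# the randomness seen by the others.  Stream ids 1 (initial activation) and
# 2 (integration noise) are consumed inside the C++ integrator; the ids
# below are the R-side consumers.

STREAM_CHOICE <- 3
STREAM_ENV <- 4
STREAM_OFFER <- 5

#' Deterministic uniform draws from a named stream
#'
#' @param seed Master seed of the simulation (non-negative integer).
#' @param stream Stream id (small integer); each consumer of randomness in a
#'   session uses its own stream.
#' @param counter Counter value, typically the trial index.
#' @param n Number of uniforms.
#' @return `n` uniforms on \[0, 1), a pure function of the arguments.
#' @export
stream_uniforms <- function(seed, stream, counter, n = 1) {
  .stream_uniforms_cpp(seed, stream, counter, as.integer(n))
}

# Evaluate `expr` under R's RNG seeded with `seed`, restoring the caller's
# RNG state afterwards (used for one-off constructions: weight matrices,
# optimizer restarts).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
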