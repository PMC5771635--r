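#' Miniature session fixtures
#'
#' Deterministic, fast-running miniature configurations (40-neuron
#' reservoir, short sessions) for tests and examples. They exercise the full
#' pipeline in seconds while keeping the task structure intact.
#'
#' @param kind `"reversal"`, `"twostage"` or `"econ"`.
#' @param seed Seed for the fixture.
#' @return A list with `config` (a [session_config()]) and `seed`.
#' @export
make_fixture <- function(kind = c("reversal", "twostage", "econ"), seed = 1) {
  kind <- match.arg(kind)
  pars <- task_parameters(kind, N = 40L)
  cfg <- switch(kind,
    reversal = session_config(reversal_config(block_length = 40),
                              n_blocks = 2,
                              reservoir_params = pars$reservoir,
                              decision_params = pars$decision),
    twostage = session_config(twostage_config(block_length = 40),
                              n_trials = 80,
                              reservoir_params = pars$reservoir,
                              decision_params = pars$decision),
    econ = session_config(econ_config(), n_trials = 80,
                          reservoir_params = pars$reservoir,
                          decision_params = pars$decision))
  list(config = cfg, seed = seed)
}
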