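fixture_session <- function(kind, seed = 1, ...) {
  fx <- make_fixture(kind, seed)
  cfg <- fx$config
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  list(cfg = cfg, seed = fx$seed)
}

test_that("a zero-trial session returns an empty log and untouched weights", {
  fx <- make_fixture("reversal")
  cfg <- fx$config
  cfg$n_trials <- 0L
  s <- run_session(cfg, seed = 1)
  expect_equal(nrow(s$log), 0)
  expect_equal(s$readout$trial_index, 0L)
})

test_that("sessions are bit-reproducible from their seed", {
  fx <- make_fixture("twostage")
  a <- run_session(fx$config, seed = 3)
  b <- run_session(fx$config, seed = 3)
  expect_identical(a$log, b$log)
  expect_identical(a$readout$W2, b$readout$W2)
  expect_identical(a$rates, b$rates)
})

test_that("no weight update is applied on the first trial", {
  fx <- make_fixture("reversal")
  cfg <- fx$config
  cfg$n_trials <- 5L
  s <- run_session(cfg, seed = 2)
  # updates happen at the end of trials 2..5 only
  expect_equal(s$readout$trial_index, 4L)
})

test_that("freezing learning pins the readout", {
  fx <- make_fixture("reversal")
  cfg <- fx$config
  cfg$n_trials <- 20L
  frozen <- session_config(cfg$task_config, n_trials = 20,
                           reservoir_params = cfg$reservoir,
                           decision_params = cfg$decision,
                           freeze_after = 0)
  s <- run_session(frozen, seed = 4)
  expect_equal(s$readout$trial_index, 0L)
  expect_identical(s$readout$W2, init_readout(cfg$reservoir$N, 2, 4)$W2)
  # partial freeze: updates stop after trial 10
  part <- session_config(cfg$task_config, n_trials = 20,
                         reservoir_params = cfg$reservoir,
                         decision_params = cfg$decision, freeze_after = 10)
  sp <- run_session(part, seed = 4)
  expect_equal(sp$readout$trial_index, 9L)  # trials 2..10
})

test_that("logged rewards agree with the environment contingency", {
  fx <- make_fixture("reversal")
  s <- run_session(fx$config, seed = 5)
  cfg <- fx$config$task_config
  expected <- vapply(seq_len(nrow(s$log)), function(t)
    reversal_step(t, s$log$choice[t], cfg), integer(1))
  expect_equal(s$log$reward, expected)
  # two-stage: reward count conserved between log and contingency bounds
  fx2 <- make_fixture("twostage")
  s2 <- run_session(fx2$config, seed = 5)
  expect_true(all(s2$log$reward %in% 0:1))
  expect_true(all(s2$log$intermediate %in% c("B1", "B2")))
})

test_that("the choice chain is consistent between trials", {
  fx <- make_fixture("reversal")
  s <- run_session(fx$config, seed = 6)
  n <- nrow(s$log)
  expect_identical(s$log$choice[-1], s$log$next_choice[-n])
})

test_that("lesioned dynamics cannot encode the outcome", {
  # with the reward input removed, the decision-time state of matched trials
  # must be identical whether or not the (invisible) outcome was rewarded
  pars <- task_parameters("reversal", N = 40)
  cfg <- reversal_config(reward_input = FALSE)
  res <- build_reservoir(pars$reservoir, 3, seed = 1)
  tr_r <- integrate_trial(res, make_reversal_schedule("A", 1, cfg), 9, trial = 4)
  tr_n <- integrate_trial(res, make_reversal_schedule("A", 0, cfg), 9, trial = 4)
  expect_identical(tr_r$rates_decision, tr_n$rates_decision)
  # sanity: with the reward input intact the two states differ
  cfg_ok <- reversal_config()
  tr_r2 <- integrate_trial(res, make_reversal_schedule("A", 1, cfg_ok), 9, trial = 4)
  expect_false(identical(tr_r2$rates_decision, tr_n$rates_decision))
})

test_that("decision-time inactivation silences the readout only", {
  pars <- task_parameters("reversal", N = 40)
  cfg <- session_config(reversal_config(block_length = 40), n_blocks = 1,
                        reservoir_params = pars$reservoir,
                        decision_params = pars$decision,
                        inactivate = 1:10, freeze_after = 0)
  s <- run_session(cfg, seed = 7)
  cfg0 <- session_config(reversal_config(block_length = 40), n_blocks = 1,
                         reservoir_params = pars$reservoir,
                         decision_params = pars$decision, freeze_after = 0)
  s0 <- run_session(cfg0, seed = 7)
  # the recorded (integration) rates of the matched first trial are
  # untouched by the inactivation (later trials diverge because the
  # manipulated readout makes different choices)
  expect_identical(s$rates[1, ], s0$rates[1, ])
  # zeroing every neuron leaves a symmetric readout: p = 1/2
  expect_equal(apply_inactivation(s$rates[1, ], 1:40), rep(0, 40))
  probs <- choice_probabilities(rep(0, 40), init_readout(40, 2, 1), beta = 4)
  expect_equal(probs, c(0.5, 0.5))
  expect_identical(apply_inactivation(s$rates[1, ], integer(0)), s$rates[1, ])
})

test_that("session configs validate their manipulations", {
  expect_error(session_config("econ", n_trials = 10,
                              lesion_reward_input = TRUE), "reward input")
  expect_error(session_config("reversal", n_blocks = 1, inactivate = 10000),
               "1..N")
  expect_error(session_config("reversal"), "n_trials")
})
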