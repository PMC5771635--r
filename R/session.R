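#' Session configuration
#'
#' Bundles a task configuration, the network and learning parameters, the
#' session length and the manipulations into one reproducible description of
#' a simulation run.
#'
#' @param task `"reversal"`, `"twostage"` or `"econ"`, or a ready-made
#'   `task_config` object.
#' @param n_trials Number of executed trials. For the reversal task,
#'   `n_blocks` may be given instead.
#' @param n_blocks Number of contingency blocks (reversal/two-stage).
#' @param reservoir_params,decision_params Optional parameter objects; by
#'   default the published per-task values ([task_parameters()]) are used.
#' @param lesion_reward_input If `TRUE`, the outcome inputs are silenced:
#'   the reward row (reversal), or the reward and non-reward rows
#'   (two-stage; set `lesion_nonreward_input = FALSE` to keep the non-reward
#'   unit).
#' @param lesion_nonreward_input Whether the two-stage lesion also removes
#'   the non-reward unit (default `TRUE`; both rows carry outcome
#'   information).
#' @param inactivate `NULL`, or an integer vector of neuron indices whose
#'   decision-time rates are zeroed in the readout computation only — the
#'   integration itself is untouched. (Use [select_inactivation_targets()]
#'   to pick neurons by selectivity label.)
#' @param freeze_after Freeze learning after this many executed trials
#'   (0 = never update; `NULL` = learn throughout).
#' @param record_weights `"block"` to snapshot the readout at block
#'   boundaries, `"none"` to skip.
#'
#' @return A `session_config` list.
#' @export
session_config <- function(task, n_trials = NULL, n_blocks = NULL,
                           reservoir_params = NULL, decision_params = NULL,
                           lesion_reward_input = FALSE,
                           lesion_nonreward_input = TRUE,
                           inactivate = NULL, freeze_after = NULL,
                           record_weights = c("block", "none")) {
  record_weights <- match.arg(record_weights)
  cfg <- if (inherits(task, "task_config")) task
         else switch(match.arg(task, c("reversal", "twostage", "econ")),
                     reversal = reversal_config(),
                     twostage = twostage_config(),
                     econ = econ_config())
  if (is.null(n_trials)) {
    if (is.null(n_blocks) || is.null(cfg$block_length))
      stop("give `n_trials` (or `n_blocks` for a block task)", call. = FALSE)
    n_trials <- n_blocks * cfg$block_length
  }
  defaults <- task_parameters(cfg$task)
  rp <- reservoir_params %||% defaults$reservoir
  dp <- decision_params %||% defaults$decision
  stopifnot(inherits(rp, "reservoir_params"), inherits(dp, "decision_params"))
  if (isTRUE(lesion_reward_input)) {
    if (cfg$task == "reversal") cfg$reward_input <- FALSE
    if (cfg$task == "twostage") {
      cfg$reward_input <- FALSE
      if (isTRUE(lesion_nonreward_input)) cfg$nonreward_input <- FALSE
    }
    if (cfg$task == "econ")
      stop("the economic choice task has no reward input to lesion",
           call. = FALSE)
  }
  if (!is.null(inactivate)) {
    inactivate <- as.integer(inactivate)
    if (any(is.na(inactivate)) || any(inactivate < 1) ||
        any(inactivate > rp$N))
      stop("`inactivate` must be neuron indices in 1..N", call. = FALSE)
  }
  structure(list(task = cfg$task, task_config = cfg,
                 n_trials = as.integer(n_trials),
                 reservoir = rp, decision = dp,
                 inactivate = inactivate,
                 freeze_after = if (is.null(freeze_after)) NULL
                                else as.integer(freeze_after),
                 record_weights = record_weights),
            class = "session_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a training session
#'
#' Executes the full trial protocol: the first trial's choice input is
#' selected at random and its reward set by the environment, with no weight
#' update; every subsequent trial presents the previous choice and outcome
#' to the reservoir, reads the decision-time rates, samples the next choice
#' from the softmax readout, queries the environment, and applies the
#' reward-modulated Hebbian update (unless learning is frozen). Everything
#' is logged per trial; the run is a pure function of `(cfg, seed)` plus the
#' optional warm-start objects.
#'
#' @param cfg A [session_config()].
#' @param seed Master seed. All randomness (network build, initial states,
#'   integration noise, environment, choice sampling, offers) derives from
#'   it through dedicated streams.
#' @param reservoir Optional pre-built [build_reservoir()] network (e.g. to
#'   continue a session); default builds one from `cfg` and `seed`.
#' @param readout Optional `readout_weights` warm start (e.g. the trained
#'   weights of a previous session).
#' @param record_rates If `TRUE` (default), keep the decision-time rate
#'   vector of every trial (needed by the selectivity and value analyses).
#' @param rate_window Optional `c(from, to)` ms; additionally record each
#'   trial's mean rate per neuron over this window (used for the post-offer
#'   value analysis).
#'
#' @return A `session_result` with elements `log` (tibble, one row per
#'   executed trial), `rates` (trials x N decision-time rates, if recorded),
#'   `rates_window`, `readout` (final weights), `weight_history`,
#'   `reservoir`, `config`, `seed`.
#' @export
run_session <- function(cfg, seed, reservoir = NULL, readout = NULL,
                        record_rates = TRUE, rate_window = NULL) {
  stopifnot(inherits(cfg, "session_config"))
  tk <- cfg$task_config
  n <- cfg$n_trials
  res <- reservoir %||% build_reservoir(cfg$reservoir, tk$n_inputs, seed,
                                        input_labels = tk$input_labels)
  ro <- readout %||% init_readout(cfg$reservoir$N, 2L, seed)
  switch(cfg$task,
         reversal = run_session_reversal(cfg, seed, res, ro, n, record_rates),
         twostage = run_session_twostage(cfg, seed, res, ro, n, record_rates),
         econ = run_session_econ(cfg, seed, res, ro, n, record_rates,
                                 rate_window))
}

# shared helpers ------------------------------------------------------------

session_can_learn <- function(cfg, trial) {
  if (trial < 2L) return(FALSE)  # no update in the first trial
  if (is.null(cfg$freeze_after)) return(TRUE)
  trial <= cfg$freeze_after
}

readout_rates <- function(y, cfg) {
  if (is.null(cfg$inactivate)) return(y)
  y[cfg$inactivate] <- 0
  y
}

new_session_result <- function(log, rates, readout, weight_history, reservoir,
                               cfg, seed, rates_window = NULL) {
  structure(list(log = log, rates = rates, rates_window = rates_window,
                 readout = readout, weight_history = weight_history,
                 reservoir = reservoir, config = cfg, seed = seed),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s task, %d trial(s), seed %s\n",
              x$config$task, nrow(x$log), format(x$seed)))
  if (nrow(x$log))
    cat(sprintf("  reward rate %.3f, final readout after %d update(s)\n",
                mean(x$log$reward), x$readout$trial_index))
  invisible(x)
}

# reversal ------------------------------------------------------------------

run_session_reversal <- function(cfg, seed, res, ro, n, record_rates) {
  tk <- cfg$task_config
  dp <- cfg$decision
  N <- cfg$reservoir$N
  choice_lv <- c("A", "B")
  choice <- character(n); reward <- integer(n)
  next_choice <- character(n); p_next <- numeric(n); e_r <- numeric(n)
  rates <- if (record_rates && n > 0) matrix(NA_real_, n, N) else NULL
  wh <- list()
  if (n == 0L)
    return(new_session_result(reversal_log(cfg, choice, reward, next_choice,
                                           p_next, e_r),
                              rates, ro, wh, res, cfg, seed))
  # trial 1: random choice input, environment-consistent reward, no update
  u0 <- stream_uniforms(seed, STREAM_CHOICE, 0, 1)
  choice[1] <- choice_lv[1L + (u0 >= 0.5)]
  reward[1] <- reversal_step(1L, choice[1], tk)
  for (t in seq_len(n)) {
    sched <- make_reversal_schedule(choice[t], reward[t], tk)
    tr <- integrate_trial(res, sched, seed, trial = t)
    y <- tr$rates_decision
    if (!is.null(rates)) rates[t, ] <- y
    probs <- choice_probabilities(readout_rates(y, cfg), ro, dp$beta,
                                  dp$convention)
    out <- sample_choice(probs, stream_uniforms(seed, STREAM_CHOICE, t, 1))
    nxt <- choice_lv[out$chosen]
    r_nxt <- reversal_step(t + 1L, nxt, tk)
    next_choice[t] <- nxt; p_next[t] <- probs[out$chosen]
    e_r[t] <- out$expected_reward
    if (session_can_learn(cfg, t))
      ro <- hebbian_update(ro, y, out, r_nxt, dp)
    if (cfg$record_weights == "block" && t %% tk$block_length == 0L)
      wh[[length(wh) + 1L]] <- ro$W2
    if (t < n) { choice[t + 1L] <- nxt; reward[t + 1L] <- r_nxt }
  }
  new_session_result(reversal_log(cfg, choice, reward, next_choice, p_next,
                                  e_r),
                     rates, ro, wh, res, cfg, seed)
}

reversal_log <- function(cfg, choice, reward, next_choice, p_next, e_r) {
  tk <- cfg$task_config
  n <- length(choice)
  trial <- seq_len(n)
  block <- (trial - 1L) %/% tk$block_length + 1L
  rewarded <- vapply(trial, reversal_rewarded, character(1), cfg = tk)
  tibble::tibble(trial = trial, block = block, rewarded_option = rewarded,
                 choice = choice, correct = as.integer(choice == rewarded),
                 reward = reward, next_choice = next_choice,
                 p_choice = p_next, expected_reward = e_r)
}

# two-stage ------------------------------------------------------------------

run_session_twostage <- function(cfg, seed, res, ro, n, record_rates) {
  tk <- cfg$task_config
  dp <- cfg$decision
  N <- cfg$reservoir$N
  choice_lv <- c("A1", "A2")
  choice <- character(n); interm <- character(n); reward <- integer(n)
  common <- logical(n); next_choice <- character(n); e_r <- numeric(n)
  rates <- if (record_rates && n > 0) matrix(NA_real_, n, N) else NULL
  wh <- list()
  if (n == 0L)
    return(new_session_result(twostage_log(cfg, choice, interm, reward,
                                           common, next_choice, e_r),
                              rates, ro, wh, res, cfg, seed))
  u0 <- stream_uniforms(seed, STREAM_CHOICE, 0, 1)
  choice[1] <- choice_lv[1L + (u0 >= 0.5)]
  st <- twostage_step(1L, choice[1], tk, stream_uniforms(seed, STREAM_ENV, 1, 2))
  interm[1] <- st$intermediate; reward[1] <- st$reward; common[1] <- st$common
  for (t in seq_len(n)) {
    sched <- make_twostage_schedule(choice[t], interm[t], reward[t], tk)
    tr <- integrate_trial(res, sched, seed, trial = t)
    y <- tr$rates_decision
    if (!is.null(rates)) rates[t, ] <- y
    probs <- choice_probabilities(readout_rates(y, cfg), ro, dp$beta,
                                  dp$convention)
    out <- sample_choice(probs, stream_uniforms(seed, STREAM_CHOICE, t, 1))
    nxt <- choice_lv[out$chosen]
    st <- twostage_step(t + 1L, nxt, tk,
                        stream_uniforms(seed, STREAM_ENV, t + 1L, 2))
    next_choice[t] <- nxt; e_r[t] <- out$expected_reward
    if (session_can_learn(cfg, t))
      ro <- hebbian_update(ro, y, out, st$reward, dp)
    if (cfg$record_weights == "block" && t %% tk$block_length == 0L)
      wh[[length(wh) + 1L]] <- ro$W2
    if (t < n) {
      choice[t + 1L] <- nxt
      interm[t + 1L] <- st$intermediate
      reward[t + 1L] <- st$reward
      common[t + 1L] <- st$common
    }
  }
  new_session_result(twostage_log(cfg, choice, interm, reward, common,
                                  next_choice, e_r),
                     rates, ro, wh, res, cfg, seed)
}

twostage_log <- function(cfg, choice, interm, reward, common, next_choice,
                         e_r) {
  tk <- cfg$task_config
  n <- length(choice)
  trial <- seq_len(n)
  block <- (trial - 1L) %/% tk$block_length + 1L
  good <- vapply(trial, twostage_good, character(1), cfg = tk)
  condition <- if (n) paste0(choice, interm, c("N", "R")[reward + 1L])
               else character(0)
  tibble::tibble(trial = trial, block = block, good_outcome = good,
                 choice = choice, intermediate = interm, common = common,
                 reward = reward, condition = condition,
                 next_choice = next_choice, expected_reward = e_r)
}

# economic choice -------------------------------------------------------------

run_session_econ <- function(cfg, seed, res, ro, n, record_rates,
                             rate_window) {
  tk <- cfg$task_config
  dp <- cfg$decision
  N <- cfg$reservoir$N
  choice_lv <- c("A", "B")
  mag_A <- numeric(n); mag_B <- numeric(n)
  choice <- character(n); reward <- numeric(n); e_r <- numeric(n)
  p_A <- numeric(n)
  rates <- if (record_rates && n > 0) matrix(NA_real_, n, N) else NULL
  rates_win <- if (!is.null(rate_window) && n > 0) matrix(NA_real_, n, N)
               else NULL
  wh <- list()
  for (t in seq_len(n)) {
    offers <- econ_draw_offers(tk, stream_uniforms(seed, STREAM_OFFER, t, 2))
    mag_A[t] <- offers[["mag_A"]]; mag_B[t] <- offers[["mag_B"]]
    sched <- make_econ_schedule(mag_A[t], mag_B[t], tk)
    tr <- integrate_trial(res, sched, seed, trial = t, window = rate_window)
    y <- tr$rates_decision
    if (!is.null(rates)) rates[t, ] <- y
    if (!is.null(rates_win)) rates_win[t, ] <- tr$rates_window
    probs <- choice_probabilities(readout_rates(y, cfg), ro, dp$beta,
                                  dp$convention)
    out <- sample_choice(probs, stream_uniforms(seed, STREAM_CHOICE, t, 1))
    choice[t] <- choice_lv[out$chosen]
    reward[t] <- if (choice[t] == "A") tk$gamma * mag_A[t] else mag_B[t]
    e_r[t] <- econ_expected_value(probs, c(mag_A[t], mag_B[t]), tk$gamma)
    p_A[t] <- probs[1]
    if (session_can_learn(cfg, t))
      ro <- hebbian_update(ro, y, out, reward[t], dp, expected_reward = e_r[t])
    if (cfg$record_weights == "block" && t %% 1000L == 0L)
      wh[[length(wh) + 1L]] <- ro$W2
  }
  log <- tibble::tibble(trial = seq_len(n), mag_A = mag_A, mag_B = mag_B,
                        choice = choice, reward = reward, p_A = p_A,
                        expected_reward = e_r)
  new_session_result(log, rates, ro, wh, res, cfg, seed,
                     rates_window = rates_win)
}
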