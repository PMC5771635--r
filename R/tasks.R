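#' Trial input schedule
#'
#' The time course of every input unit over one trial, plus the time at
#' which the readout is taken. Columns are integration steps: column `j`
#' holds the drive applied during `((j-1)*dt, j*dt]` ms.
#'
#' @param inputs `M x T` matrix of input-unit drive in \[0, 1\].
#' @param decision_time Read-off time in ms.
#' @param labels Input-unit names (length M).
#' @return A `trial_schedule` object.
#' @export
trial_schedule <- function(inputs, decision_time, labels = rownames(inputs)) {
  inputs <- as.matrix(inputs)
  if (any(inputs < 0 | inputs > 1)) stop("input drive must lie in [0, 1]",
                                         call. = FALSE)
  if (decision_time > ncol(inputs))
    stop("decision time exceeds the trial duration", call. = FALSE)
  if (!is.null(labels)) rownames(inputs) <- labels
  structure(list(inputs = inputs, decision_time = decision_time,
                 labels = labels),
            class = "trial_schedule")
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> %d input units x %d ms, decision at %d ms\n",
              nrow(x$inputs), ncol(x$inputs), x$decision_time))
  invisible(x)
}

# fill a window (from, to] given in ms with value 1
window_cols <- function(from, to) seq.int(from + 1L, to)

## ---- reversal learning ----------------------------------------------------

#' Reversal-learning task configuration
#'
#' Two options; one is rewarded deterministically, and the contingency flips
#' every `block_length` trials. The previous trial's choice and its reward
#' are presented concurrently as unit-amplitude inputs during the stimulus
#' window, and the choice for the next trial is read at `decision_time`.
#'
#' @param block_length Trials per contingency block.
#' @param stim_window `c(on, off)` of the input activation in ms.
#' @param decision_time Read-off time in ms (also the trial duration).
#' @param criterion_initial,criterion_reversal `c(m, n)` sliding-window
#'   learning criteria (m correct of n successive trials) for the first
#'   block and for later blocks.
#' @param reward_input If `FALSE`, the reward input row is silenced — the
#'   lesion model of learning without a functioning stimulus-reward
#'   association pathway.
#' @param first_rewarded Which option is rewarded in block 1.
#' @return A `reversal_config` list.
#' @export
reversal_config <- function(block_length = 100, stim_window = c(200, 700),
                            decision_time = 900,
                            criterion_initial = c(28, 30),
                            criterion_reversal = c(24, 30),
                            reward_input = TRUE,
                            first_rewarded = c("A", "B")) {
  first_rewarded <- match.arg(first_rewarded)
  stopifnot(stim_window[1] >= 0, stim_window[2] > stim_window[1],
            decision_time >= stim_window[2],
            criterion_initial[1] <= criterion_initial[2],
            criterion_reversal[1] <= criterion_reversal[2],
            criterion_initial[2] <= block_length)
  structure(list(task = "reversal", block_length = as.integer(block_length),
                 stim_window = stim_window, decision_time = decision_time,
                 trial_duration = decision_time,
                 criterion_initial = criterion_initial,
                 criterion_reversal = criterion_reversal,
                 reward_input = isTRUE(reward_input),
                 first_rewarded = first_rewarded,
                 input_labels = c("A", "B", "R"), n_inputs = 3L),
            class = c("reversal_config", "task_config"))
}

#' Rewarded option of a reversal block
#' @keywords internal
reversal_rewarded <- function(trial, cfg) {
  block <- (trial - 1L) %/% cfg$block_length + 1L
  sides <- c("A", "B")
  start <- match(cfg$first_rewarded, sides)
  sides[(start + block) %% 2L + 1L]
}

#' Environment step of the reversal task
#'
#' @param trial Trial index at which the choice is executed.
#' @param choice `"A"` or `"B"`.
#' @param cfg A [reversal_config()].
#' @return Reward (0/1): 1 iff the choice matches the block's rewarded side.
#' @export
reversal_step <- function(trial, choice, cfg) {
  as.integer(choice == reversal_rewarded(trial, cfg))
}

#' Input schedule of a reversal trial
#'
#' The unit of the previously chosen option and (iff rewarded and the reward
#' input is intact) the reward unit are set to 1 during the stimulus window;
#' everything else is 0.
#'
#' @param prev_choice `"A"` or `"B"` — the choice executed this trial.
#' @param prev_reward 0/1 — its reward outcome.
#' @param cfg A [reversal_config()].
#' @return A [trial_schedule()] with rows A, B, R.
#' @export
make_reversal_schedule <- function(prev_choice, prev_reward, cfg) {
  inputs <- matrix(0, 3, cfg$trial_duration,
                   dimnames = list(cfg$input_labels, NULL))
  win <- window_cols(cfg$stim_window[1], cfg$stim_window[2])
  inputs[match(prev_choice, c("A", "B")), win] <- 1
  if (prev_reward == 1 && cfg$reward_input) inputs["R", win] <- 1
  trial_schedule(inputs, cfg$decision_time, cfg$input_labels)
}

## ---- two-stage Markov decision task ---------------------------------------

#' Two-stage Markov decision task configuration
#'
#' First-stage options `A1`/`A2` lead to intermediate outcomes `B1`/`B2`
#' with fixed probabilities (`A1 -> B1` and `A2 -> B2` with probability
#' `common_prob`); only the intermediate outcome determines reward
#' (probability `reward_prob_hi` for the currently good outcome,
#' `reward_prob_lo` for the other), and that contingency reverses every
#' `block_length` trials while the transition structure never changes.
#' Events are presented sequentially: the chosen A unit, then the observed B
#' unit, then the reward or non-reward unit.
#'
#' @param common_prob Probability of the common transition.
#' @param reward_prob_hi,reward_prob_lo Reward probabilities of the good and
#'   bad intermediate outcome.
#' @param block_length Trials per reward-contingency block.
#' @param A_window,B_window,R_window Activation windows in ms.
#' @param decision_time Read-off time in ms (also the trial duration).
#' @param event_order `"A-first"` (default) or `"B-first"` (a variant that
#'   swaps the A and B windows to control for recency).
#' @param reward_input,nonreward_input Silence the reward / non-reward input
#'   rows (`reward_input = FALSE` with `nonreward_input = FALSE` is the full
#'   outcome-pathway lesion; setting only `reward_input = FALSE` removes the
#'   reward unit alone).
#' @param good_first Which intermediate outcome is rewarded at `reward_prob_hi`
#'   in block 1.
#' @return A `twostage_config` list.
#' @export
twostage_config <- function(common_prob = 0.8, reward_prob_hi = 0.8,
                            reward_prob_lo = 0.2, block_length = 50,
                            A_window = c(200, 700), B_window = c(700, 1200),
                            R_window = c(1200, 1700), decision_time = 1900,
                            event_order = c("A-first", "B-first"),
                            reward_input = TRUE, nonreward_input = TRUE,
                            good_first = c("B1", "B2")) {
  event_order <- match.arg(event_order)
  good_first <- match.arg(good_first)
  stopifnot(common_prob >= 0, common_prob <= 1,
            reward_prob_hi >= 0, reward_prob_hi <= 1,
            reward_prob_lo >= 0, reward_prob_lo <= 1,
            decision_time >= max(A_window, B_window, R_window))
  structure(list(task = "twostage", common_prob = common_prob,
                 reward_prob_hi = reward_prob_hi,
                 reward_prob_lo = reward_prob_lo,
                 block_length = as.integer(block_length),
                 A_window = A_window, B_window = B_window,
                 R_window = R_window, decision_time = decision_time,
                 trial_duration = decision_time, event_order = event_order,
                 reward_input = isTRUE(reward_input),
                 nonreward_input = isTRUE(nonreward_input),
                 good_first = good_first,
                 input_labels = c("A1", "A2", "B1", "B2", "R", "N"),
                 n_inputs = 6L),
            class = c("twostage_config", "task_config"))
}

#' Good intermediate outcome of a two-stage block
#' @keywords internal
twostage_good <- function(trial, cfg) {
  block <- (trial - 1L) %/% cfg$block_length + 1L
  outs <- c("B1", "B2")
  start <- match(cfg$good_first, outs)
  outs[(start + block) %% 2L + 1L]
}

#' Environment step of the two-stage task
#'
#' Draws the intermediate outcome (common with probability `common_prob`,
#' rare otherwise) and then the reward given that outcome's current
#' contingency.
#'
#' @param trial Trial index at which the choice is executed.
#' @param choice `"A1"` or `"A2"`.
#' @param cfg A [twostage_config()].
#' @param u Two uniforms on \[0,1) (transition, reward), e.g. from the
#'   environment stream.
#' @return List with `intermediate` (`"B1"`/`"B2"`), `reward` (0/1) and
#'   `common` (logical).
#' @export
twostage_step <- function(trial, choice, cfg, u) {
  common_out <- if (choice == "A1") "B1" else "B2"
  rare_out <- if (choice == "A1") "B2" else "B1"
  common <- u[1] < cfg$common_prob
  intermediate <- if (common) common_out else rare_out
  p_r <- if (intermediate == twostage_good(trial, cfg)) cfg$reward_prob_hi
         else cfg$reward_prob_lo
  list(intermediate = intermediate, reward = as.integer(u[2] < p_r),
       common = common)
}

#' Input schedule of a two-stage trial
#'
#' Activates the chosen first-stage unit, the observed intermediate unit and
#' the reward unit (or the non-reward unit when no reward was obtained)
#' sequentially in their windows.
#'
#' @param choice `"A1"` or `"A2"`.
#' @param intermediate `"B1"` or `"B2"`.
#' @param reward 0/1.
#' @param cfg A [twostage_config()].
#' @return A [trial_schedule()] with rows A1, A2, B1, B2, R, N.
#' @export
make_twostage_schedule <- function(choice, intermediate, reward, cfg) {
  inputs <- matrix(0, 6, cfg$trial_duration,
                   dimnames = list(cfg$input_labels, NULL))
  a_win <- cfg$A_window; b_win <- cfg$B_window
  if (cfg$event_order == "B-first") { tmp <- a_win; a_win <- b_win; b_win <- tmp }
  inputs[choice, window_cols(a_win[1], a_win[2])] <- 1
  inputs[intermediate, window_cols(b_win[1], b_win[2])] <- 1
  r_win <- window_cols(cfg$R_window[1], cfg$R_window[2])
  if (reward == 1) {
    if (cfg$reward_input) inputs["R", r_win] <- 1
  } else {
    if (cfg$nonreward_input) inputs["N", r_win] <- 1
  }
  trial_schedule(inputs, cfg$decision_time, cfg$input_labels)
}

## ---- value-based economic choice ------------------------------------------

#' Economic choice task configuration
#'
#' Each trial offers magnitudes of two juices A and B; juice A is worth
#' `gamma` times juice B per unit of magnitude. Input units carry the offer
#' magnitudes with range adaptation over the block's offer grid and a
#' sensory-like temporal profile (sigmoidal rise and decay, or a step
#' function variant). Offers are drawn uniformly from the grid, excluding
#' the (0, 0) pair.
#'
#' @param gamma Relative value of juice A in units of juice B.
#' @param offers_A,offers_B Candidate offer magnitudes per juice.
#' @param stim_window `c(on, off)` of the offer presentation in ms.
#' @param decision_time Read-off time in ms (also the trial duration).
#' @param rise_center,rise_slope,decay_center,decay_slope Constants of the
#'   sigmoid profile `g(t) = 1 / ((1 + exp(-(t-rise_center)/rise_slope)) *
#'   (1 + exp((t-decay_center)/decay_slope)))`, with `t` absolute trial time
#'   in ms.
#' @param profile `"sigmoid"` (default) or `"step"` (flat drive over the
#'   window).
#' @return An `econ_config` list.
#' @export
econ_config <- function(gamma = 2, offers_A = 0:3, offers_B = 0:8,
                        stim_window = c(300, 1300), decision_time = 1400,
                        rise_center = 475, rise_slope = 30,
                        decay_center = 700, decay_slope = 100,
                        profile = c("sigmoid", "step")) {
  profile <- match.arg(profile)
  stopifnot(gamma > 0, all(offers_A >= 0), all(offers_B >= 0),
            decision_time >= stim_window[2])
  structure(list(task = "econ", gamma = gamma,
                 offers_A = offers_A, offers_B = offers_B,
                 stim_window = stim_window, decision_time = decision_time,
                 trial_duration = decision_time,
                 rise_center = rise_center, rise_slope = rise_slope,
                 decay_center = decay_center, decay_slope = decay_slope,
                 profile = profile,
                 input_labels = c("offerA", "offerB"), n_inputs = 2L),
            class = c("econ_config", "task_config"))
}

# raw temporal kernel of the offer inputs at absolute trial time t (ms)
econ_profile_kernel <- function(t, cfg) {
  if (cfg$profile == "step") return(rep(1, length(t)))
  1 / ((1 + exp(-(t - cfg$rise_center) / cfg$rise_slope)) *
       (1 + exp((t - cfg$decay_center) / cfg$decay_slope)))
}

#' Offer-input drive at time t
#'
#' Range-adapted drive of an offer-magnitude input unit:
#' `f(t) = (mag - mag_min) * g(t) / ((mag_max - mag_min) * max_t g(t))`,
#' zero outside the stimulus window. The block-maximal offer reaches the
#' kernel's peak; the block-minimal offer (always 0 here) is silent.
#'
#' @param t Time(s) in ms (absolute trial time).
#' @param mag Offer magnitude this trial.
#' @param mag_max,mag_min Block-maximal and -minimal magnitudes of this
#'   juice.
#' @param cfg An [econ_config()].
#' @return Drive value(s) in \[0, 1\].
#' @export
econ_input_profile <- function(t, mag, mag_max, mag_min, cfg) {
  if (mag_max <= mag_min)
    stop("degenerate offer range: mag_max must exceed mag_min", call. = FALSE)
  win <- t > cfg$stim_window[1] & t <= cfg$stim_window[2]
  tt <- seq.int(cfg$stim_window[1] + 1L, cfg$stim_window[2])
  peak <- max(econ_profile_kernel(tt, cfg))
  out <- numeric(length(t))
  out[win] <- (mag - mag_min) * econ_profile_kernel(t[win], cfg) /
    ((mag_max - mag_min) * peak)
  out
}

#' Input schedule of an economic choice trial
#'
#' @param mag_A,mag_B Offer magnitudes this trial.
#' @param cfg An [econ_config()].
#' @return A [trial_schedule()] with rows offerA, offerB.
#' @export
make_econ_schedule <- function(mag_A, mag_B, cfg) {
  t <- seq_len(cfg$trial_duration)
  inputs <- rbind(
    offerA = econ_input_profile(t, mag_A, max(cfg$offers_A), min(cfg$offers_A), cfg),
    offerB = econ_input_profile(t, mag_B, max(cfg$offers_B), min(cfg$offers_B), cfg))
  trial_schedule(inputs, cfg$decision_time, cfg$input_labels)
}

#' Draw one offer pair
#'
#' Uniform over the configured grid excluding the (0, 0) pair.
#'
#' @param cfg An [econ_config()].
#' @param u Two uniforms on \[0,1).
#' @return Named numeric `c(mag_A, mag_B)`.
#' @export
econ_draw_offers <- function(cfg, u) {
  repeat {
    mag_A <- cfg$offers_A[1L + floor(u[1] * length(cfg$offers_A))]
    mag_B <- cfg$offers_B[1L + floor(u[2] * length(cfg$offers_B))]
    if (mag_A > 0 || mag_B > 0) break
    # re-derive fresh uniforms deterministically from the pair
    u <- (u * 104729 + c(0.123456789, 0.987654321)) %% 1
  }
  c(mag_A = mag_A, mag_B = mag_B)
}

#' Expected reward value of the economic choice
#'
#' `E(r) = p_A * (gamma * m_A) + p_B * m_B`: the probability-weighted value
#' of the two offers, in units of juice B. The obtained reward on choosing A
#' is `gamma * m_A`, on choosing B it is `m_B`.
#'
#' @param probs `c(p_A, p_B)` choice probabilities.
#' @param mags `c(m_A, m_B)` offer magnitudes.
#' @param gamma Relative value of juice A.
#' @return The scalar expected value.
#' @export
econ_expected_value <- function(probs, mags, gamma) {
  probs[[1]] * (gamma * mags[[1]]) + probs[[2]] * mags[[2]]
}
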