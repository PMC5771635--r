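#' Initialize the plastic readout weights
#'
#' Entries are drawn uniform \[0,1\] and each output column is normalized to
#' unit Euclidean norm, the constraint the Hebbian rule re-imposes after
#' every update.
#'
#' @param N Number of reservoir neurons (rows).
#' @param K Number of output units (columns); 2 in all tasks.
#' @param seed Integer seed (pure function of arguments).
#' @return A `readout_weights` object: matrix `W2` (`N x K`) with unit-norm
#'   columns and an update counter `trial_index`.
#' @export
init_readout <- function(N, K = 2, seed = 1) {
  N <- as.integer(N); K <- as.integer(K)
  if (is.na(N) || N < 1 || is.na(K) || K < 1)
    stop("`N` and `K` must be positive counts", call. = FALSE)
  W2 <- with_seed(seed, matrix(stats::runif(N * K), N, K))
  W2 <- normalize_columns(W2)
  structure(list(W2 = W2, trial_index = 0L), class = "readout_weights")
}

normalize_columns <- function(W) {
  nrm <- sqrt(colSums(W^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero output column",
                          call. = FALSE)
  sweep(W, 2, nrm, "/")
}

#' @export
print.readout_weights <- function(x, ...) {
  cat(sprintf("<readout_weights> %d x %d, %d update(s) applied\n",
              nrow(x$W2), ncol(x$W2), x$trial_index))
  invisible(x)
}

#' Softmax choice probabilities from decision-time rates
#'
#' The drive of output `k` is `v_k = sum_i W2[i,k] * y_i`; choice
#' probabilities are `p_k = exp(s * beta * v_k) / sum_l exp(s * beta * v_l)`
#' with `s = +1` under the default `"preferred"` convention and `s = -1`
#' under `"literal"` (see [decision_params()]). Computed with a max-shift so
#' that `|beta * v|` up to ~700 cannot overflow.
#'
#' @param y Length-N decision-time rate vector (after any inactivation).
#' @param readout A `readout_weights` object (or a bare `N x K` matrix).
#' @param beta Inverse temperature.
#' @param convention `"preferred"` or `"literal"`.
#' @return Length-K probability vector summing to 1.
#' @export
choice_probabilities <- function(y, readout, beta,
                                 convention = c("preferred", "literal")) {
  convention <- match.arg(convention)
  W2 <- if (inherits(readout, "readout_weights")) readout$W2 else readout
  if (length(y) != nrow(W2))
    stop("rate vector length does not match the readout", call. = FALSE)
  v <- drop(crossprod(W2, y))
  if (any(!is.finite(v))) stop("non-finite readout drive", call. = FALSE)
  s <- if (convention == "preferred") 1 else -1
  z <- s * beta * v
  e <- exp(z - max(z))
  e / sum(e)
}

#' Sample a choice from softmax probabilities
#'
#' Inverse-CDF categorical sampling. The expected reward attached to the
#' outcome is the probability of the sampled choice, which is the expected
#' value used by the learning rule in the binary-reward tasks; the economic
#' choice task overrides it with its magnitude-weighted expectation
#' ([econ_expected_value()]).
#'
#' @param probs Probability vector (must sum to 1).
#' @param u A single uniform \[0,1) variate driving the draw (supply one
#'   from a dedicated stream for reproducibility).
#' @return A `choice_outcome`: `chosen` (1-based index), `probs`, one-hot
#'   `z`, and `expected_reward = probs[chosen]`.
#' @export
sample_choice <- function(probs, u) {
  if (abs(sum(probs) - 1) > 1e-8 || any(probs < 0))
    stop("`probs` must be a probability vector", call. = FALSE)
  chosen <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
  chosen <- min(chosen, length(probs))
  z <- numeric(length(probs)); z[chosen] <- 1
  structure(list(chosen = chosen, probs = probs, z = z,
                 expected_reward = probs[[chosen]]),
            class = "choice_outcome")
}

#' Reward-modulated Hebbian update of the readout
#'
#' Applies `dW[i,k] = eta * (r - E[r]) * (y_i - y_th) * z_k` — reward
#' prediction error times thresholded presynaptic rate, gated to the chosen
#' output — then renormalizes every output column to unit Euclidean norm,
#' which stops the weights from growing without bound. Unchosen columns are
#' touched only by their (no-op) renormalization.
#'
#' @param readout A `readout_weights` object.
#' @param y Decision-time rate vector of the same trial.
#' @param outcome The `choice_outcome` of the trial (supplies `z` and, unless
#'   `expected_reward` is given, `E[r]`).
#' @param r Obtained reward.
#' @param params A [decision_params()] object (supplies `eta` and `y_th`).
#' @param expected_reward Optional override of `E[r]` (used by the economic
#'   choice task).
#' @return The updated `readout_weights`.
#' @export
hebbian_update <- function(readout, y, outcome, r, params,
                           expected_reward = NULL) {
  stopifnot(inherits(readout, "readout_weights"),
            inherits(outcome, "choice_outcome"))
  er <- if (is.null(expected_reward)) outcome$expected_reward else expected_reward
  if (!is.finite(r) || !is.finite(er))
    stop("non-finite reward or expected reward", call. = FALSE)
  W2 <- readout$W2
  k <- outcome$chosen
  W2[, k] <- W2[, k] + params$eta * (r - er) * (y - params$y_th)
  readout$W2 <- normalize_columns(W2)
  readout$trial_index <- readout$trial_index + 1L
  readout
}
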