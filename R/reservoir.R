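#' Build the fixed random reservoir
#'
#' Constructs the sparse recurrent weight matrix and the input-projection
#' matrix of the state-encoding layer. Recurrent entries are zero with
#' probability `1 - p`; nonzero entries are independent Gaussians with
#' variance `1/(p*N)` (the gain `g` is applied once, in the dynamics, so the
#' effective coupling variance is `g^2/(p*N)`; see the `double_gain` flag of
#' [reservoir_params()] for the literal double-gain reading). Input weights
#' are zero with probability `1 - p_IR`, else Gaussian with standard
#' deviation `g_IR`. Both matrices are fixed for the lifetime of the
#' network; learning only ever touches the readout.
#'
#' @param params A [reservoir_params()] object.
#' @param num_inputs Number of input units (3 for reversal learning, 6 for
#'   the two-stage task, 2 for economic choice).
#' @param seed Integer seed; construction is a pure function of
#'   `(params, num_inputs, seed)`.
#' @param input_labels Optional character labels for the input units.
#'
#' @return A `reservoir` object holding `W_rec` (sparse `dgCMatrix`), `W_in`
#'   (dense `N x num_inputs`), the parameters and the seed.
#' @examples
#' res <- build_reservoir(reservoir_params(N = 50), num_inputs = 3, seed = 1)
#' Matrix::nnzero(res$W_rec) / 50^2  # close to p = 0.1
#' @export
build_reservoir <- function(params, num_inputs, seed, input_labels = NULL) {
  stopifnot(inherits(params, "reservoir_params"))
  validate_reservoir_params(params)
  num_inputs <- as.integer(num_inputs)
  if (is.na(num_inputs) || num_inputs < 1)
    stop("`num_inputs` must be a positive count", call. = FALSE)
  if (!is.null(input_labels) && length(input_labels) != num_inputs)
    stop("`input_labels` must have length `num_inputs`", call. = FALSE)
  N <- params$N
  rec_sd <- if (params$double_gain) params$g / sqrt(params$p * N)
            else 1 / sqrt(params$p * N)
  mats <- with_seed(seed, {
    mask <- stats::runif(N * N) < params$p
    w <- numeric(N * N)
    w[mask] <- stats::rnorm(sum(mask), 0, rec_sd)
    W_rec <- Matrix::Matrix(matrix(w, N, N), sparse = TRUE)
    mask_in <- stats::runif(N * num_inputs) < params$p_IR
    w_in <- numeric(N * num_inputs)
    w_in[mask_in] <- stats::rnorm(sum(mask_in), 0, params$g_IR)
    list(W_rec = W_rec, W_in = matrix(w_in, N, num_inputs))
  })
  # CSR of W_rec (= CSC of its transpose), kept alongside for the integrator
  Wt <- methods::as(Matrix::t(mats$W_rec), "CsparseMatrix")
  structure(list(W_rec = mats$W_rec, W_in = mats$W_in,
                 csr = list(row_ptr = Wt@p, col_idx = Wt@i, values = Wt@x),
                 params = params, num_inputs = num_inputs,
                 input_labels = input_labels, seed = seed),
            class = "reservoir")
}

#' @export
print.reservoir <- function(x, ...) {
  cat(sprintf("<reservoir> N = %d neurons, %d input units, seed = %s\n",
              x$params$N, x$num_inputs, format(x$seed)),
      sprintf("  W_rec: %d nonzero of %d (density %.3f); W_in: %d nonzero\n",
              length(x$csr$values), x$params$N^2,
              length(x$csr$values) / x$params$N^2, sum(x$W_in != 0)))
  invisible(x)
}

#' Firing-rate transfer function
#'
#' Maps the activation variable to a firing rate bounded in
#' \[`ymin`, `ymax`\]: `y0 + y0*tanh(x/y0)` for `x <= 0` and
#' `y0 + (ymax-y0)*tanh(x/(ymax-y0))` for `x > 0`. Continuous and monotone,
#' with `rate_transfer(0) = y0`.
#'
#' @param x Activation values (vectorized).
#' @param y0 Baseline rate.
#' @param ymax Maximal rate.
#' @return Rates, same shape as `x`.
#' @examples
#' rate_transfer(0)       # 0.1, the baseline
#' rate_transfer(-0.1)    # 0.1 + 0.1*tanh(-1)
#' @export
rate_transfer <- function(x, y0 = 0.1, ymax = 1) {
  out <- .rate_transfer_cpp(as.numeric(x), y0, ymax)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Integrate the reservoir over one trial
#'
#' Runs the Euler dynamics
#' `x <- x + (dt/tau) * (-x + g * W_rec y + W_in I(t) + sigma_noise * u)`
#' from a fresh Gaussian initial state, with `u` a per-neuron, per-step
#' uniform \[0,1\] draw and `y = rate_transfer(x)`. The activation is reset
#' at the beginning of every trial; no state carries over between trials.
#'
#' @param reservoir A [build_reservoir()] network.
#' @param schedule A [trial_schedule()] (input-unit drive over the trial and
#'   the decision read-off time).
#' @param seed Master seed of the enclosing session.
#' @param trial Trial counter; together with `seed` it selects the noise
#'   stream, so that re-running a trial reproduces it exactly.
#' @param record_trace If `TRUE`, keep the full time-by-neuron rate matrix.
#' @param window Optional `c(from, to)` times in ms; if given, the mean rate
#'   per neuron over steps in `(from, to]` is returned as `rates_window`.
#'
#' @return An `activity_trace`: list with `rates_decision` (length-N rates
#'   at the decision read-off), optionally `rates` (T x N) and `rates_window`,
#'   plus `times` and `decision_index`.
#' @export
integrate_trial <- function(reservoir, schedule, seed, trial = 1,
                            record_trace = FALSE, window = NULL) {
  stopifnot(inherits(reservoir, "reservoir"), inherits(schedule, "trial_schedule"))
  prm <- reservoir$params
  if (nrow(schedule$inputs) != reservoir$num_inputs)
    stop("schedule has ", nrow(schedule$inputs), " input rows but the ",
         "reservoir expects ", reservoir$num_inputs, call. = FALSE)
  n_steps <- ncol(schedule$inputs)
  dec_idx <- as.integer(round(schedule$decision_time / prm$dt))
  if (dec_idx > n_steps)
    stop("schedule shorter than its decision time", call. = FALSE)
  need_trace <- record_trace || !is.null(window)
  out <- .integrate_trial_cpp(
    reservoir$csr$row_ptr, reservoir$csr$col_idx, reservoir$csr$values,
    reservoir$W_in, schedule$inputs,
    prm$g, prm$tau, prm$dt, prm$sigma_noise, prm$sigma_ini,
    prm$y0, prm$ymax, prm$zero_mean_noise,
    seed, trial, dec_idx, need_trace)
  trace <- list(rates_decision = out$rates_decision,
                times = seq_len(n_steps) * prm$dt,
                decision_index = dec_idx)
  if (!is.null(window)) {
    idx <- which(trace$times > window[1] & trace$times <= window[2])
    if (!length(idx)) stop("empty rate window", call. = FALSE)
    trace$rates_window <- colMeans(out$trace[idx, , drop = FALSE])
    trace$window <- window
  }
  if (record_trace) trace$rates <- out$trace
  structure(trace, class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> %d steps, decision at step %d\n",
              length(x$times), x$decision_index))
  invisible(x)
}
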