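#' Reservoir (state-encoding layer) parameters
#'
#' Collects the fixed parameters of the random recurrent network: its size
#' and sparsity, the recurrent gain, the integration time constant, noise
#' amplitudes, the input-projection statistics, and the rate-transfer
#' constants. Per-task presets reproduce the published parameter tables via
#' [task_parameters()].
#'
#' @param N Number of reservoir neurons.
#' @param p Recurrent connection probability.
#' @param g Recurrent gain, the control parameter of the reservoir dynamics.
#' @param tau Membrane time constant in ms.
#' @param dt Euler integration step in ms.
#' @param sigma_noise Amplitude of the per-step, per-neuron uniform noise.
#' @param sigma_ini Standard deviation of the Gaussian initial activation at
#'   trial start.
#' @param g_IR Standard deviation of the nonzero input-projection weights.
#' @param p_IR Input connection probability.
#' @param y0 Baseline firing rate.
#' @param ymin,ymax Minimal and maximal firing rate.
#' @param double_gain If `TRUE`, sample the recurrent weights with variance
#'   `g^2/(p*N)` *and* multiply by `g` in the dynamics (the literal reading
#'   of the printed equations, which applies the gain twice). The default
#'   samples with variance `1/(p*N)` so that the effective coupling variance
#'   is `g^2/(p*N)` with `g` acting once as the control parameter.
#' @param zero_mean_noise If `TRUE`, centre the per-step uniform noise at
#'   zero. The default keeps the printed uniform \[0,1\] draw, which has a
#'   small positive mean.
#'
#' @return A `reservoir_params` list.
#' @seealso [task_parameters()], [build_reservoir()]
#' @export
reservoir_params <- function(N = 500, p = 0.1, g = 2, tau = 100, dt = 1,
                             sigma_noise = 0.01, sigma_ini = 0.01,
                             g_IR = 4, p_IR = 0.2,
                             y0 = 0.1, ymin = 0, ymax = 1,
                             double_gain = FALSE, zero_mean_noise = FALSE) {
  prm <- list(N = as.integer(N), p = p, g = g, tau = tau, dt = dt,
              sigma_noise = sigma_noise, sigma_ini = sigma_ini,
              g_IR = g_IR, p_IR = p_IR, y0 = y0, ymin = ymin, ymax = ymax,
              double_gain = isTRUE(double_gain),
              zero_mean_noise = isTRUE(zero_mean_noise))
  validate_reservoir_params(prm)
  structure(prm, class = "reservoir_params")
}

validate_reservoir_params <- function(prm) {
  stop_if <- function(bad, field, why) {
    if (bad) stop("invalid reservoir parameter `", field, "`: ", why,
                  call. = FALSE)
  }
  stop_if(!is.numeric(prm$N) || prm$N < 1, "N", "must be a positive count")
  stop_if(prm$p <= 0 || prm$p > 1, "p", "must be in (0, 1]")
  stop_if(prm$p_IR <= 0 || prm$p_IR > 1, "p_IR", "must be in (0, 1]")
  stop_if(prm$tau <= 0, "tau", "must be positive")
  stop_if(prm$dt <= 0, "dt", "must be positive")
  stop_if(prm$dt > prm$tau, "dt", "must not exceed tau")
  stop_if(prm$sigma_noise < 0, "sigma_noise", "must be non-negative")
  stop_if(prm$sigma_ini < 0, "sigma_ini", "must be non-negative")
  stop_if(prm$ymin > prm$y0 || prm$y0 > prm$ymax, "y0",
          "must satisfy ymin <= y0 <= ymax")
  invisible(prm)
}

#' Decision-readout parameters
#'
#' @param beta Softmax inverse temperature.
#' @param eta Learning rate of the reward-modulated Hebbian rule.
#' @param y_th Presynaptic rate threshold of the Hebbian rule: neurons firing
#'   above `y_th` at decision time strengthen their connection to the chosen
#'   output after a positive reward prediction error, neurons below weaken it.
#' @param convention Sign convention of the softmax. `"preferred"` (default)
#'   uses `exp(+beta * v)` so that strengthening an output's drive increases
#'   its choice probability; `"literal"` uses `exp(-beta * v)` exactly as
#'   printed in the source equations, under which learning would act in the
#'   wrong direction (presumed typo; provided for comparison).
#'
#' @return A `decision_params` list.
#' @export
decision_params <- function(beta = 4, eta = 0.001, y_th = 0.2,
                            convention = c("preferred", "literal")) {
  convention <- match.arg(convention)
  if (beta < 0) stop("invalid decision parameter `beta`: must be non-negative",
                     call. = FALSE)
  if (eta < 0) stop("invalid decision parameter `eta`: must be non-negative",
                    call. = FALSE)
  if (y_th < 0 || y_th > 1)
    stop("invalid decision parameter `y_th`: must be in [0, 1]", call. = FALSE)
  structure(list(beta = beta, eta = eta, y_th = y_th, convention = convention),
            class = "decision_params")
}

#' Published per-task parameter sets
#'
#' Returns the reservoir and decision parameters used for each behavioural
#' paradigm: reversal learning (`tau` 100 ms, `g` 2, `beta` 4, `eta` 0.001,
#' `sigma_noise` 0.01, `sigma_ini` 0.01, `g_IR` 4), the two-stage Markov
#' decision task (`tau` 500 ms, `g` 2.25, `beta` 2, `eta` 0.001, `g_IR` 2)
#' and the value-based economic choice task (`tau` 100 ms, `g` 2.5, `beta`
#' 4, `eta` 0.005, `sigma_noise` 0.05, `sigma_ini` 0.2, `g_IR` 2). All tasks
#' share `N` 500, `p` 0.1, `p_IR` 0.2 and `y_th` 0.2.
#'
#' @param task One of `"reversal"`, `"twostage"`, `"econ"`.
#' @param ... Overrides passed on to [reservoir_params()] or
#'   [decision_params()] (matched by name).
#'
#' @return A list with elements `reservoir` and `decision`.
#' @export
task_parameters <- function(task = c("reversal", "twostage", "econ"), ...) {
  task <- match.arg(task)
  defaults <- switch(task,
    reversal = list(res = list(g = 2, tau = 100, sigma_noise = 0.01,
                               sigma_ini = 0.01, g_IR = 4),
                    dec = list(beta = 4, eta = 0.001)),
    twostage = list(res = list(g = 2.25, tau = 500, sigma_noise = 0.01,
                               sigma_ini = 0.01, g_IR = 2),
                    dec = list(beta = 2, eta = 0.001)),
    econ = list(res = list(g = 2.5, tau = 100, sigma_noise = 0.05,
                           sigma_ini = 0.2, g_IR = 2),
                dec = list(beta = 4, eta = 0.005))
  )
  dots <- list(...)
  res_names <- names(formals(reservoir_params))
  dec_names <- names(formals(decision_params))
  unknown <- setdiff(names(dots), c(res_names, dec_names))
  if (length(unknown))
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  res_args <- utils::modifyList(defaults$res, dots[intersect(names(dots), res_names)])
  dec_args <- utils::modifyList(defaults$dec, dots[intersect(names(dots), dec_names)])
  list(reservoir = do.call(reservoir_params, res_args),
       decision = do.call(decision_params, dec_args))
}

#' @export
print.reservoir_params <- function(x, ...) {
  cat("<reservoir_params>",
      sprintf("N = %d, p = %.3g, g = %.3g, tau = %.5g ms, dt = %.3g ms",
              x$N, x$p, x$g, x$tau, x$dt),
      sprintf("sigma_noise = %.3g, sigma_ini = %.3g, g_IR = %.3g, p_IR = %.3g",
              x$sigma_noise, x$sigma_ini, x$g_IR, x$p_IR),
      sprintf("rates: y0 = %.3g in [%.3g, %.3g]", x$y0, x$ymin, x$ymax),
      sep = "\n")
  invisible(x)
}

#' @export
print.decision_params <- function(x, ...) {
  cat("<decision_params>",
      sprintf("beta = %.3g, eta = %.3g, y_th = %.3g, convention = %s",
              x$beta, x$eta, x$y_th, x$convention),
      sep = "\n")
  invisible(x)
}
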