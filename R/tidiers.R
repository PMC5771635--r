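#' Tidy a hybrid model fit
#'
#' @param x A `hybrid_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter with `term` and `estimate`.
#' @export
tidy.hybrid_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha1", "alpha2", "lambda", "w"),
                 estimate = c(x$alpha1, x$alpha2, x$lambda, x$w))
}

#' @rdname tidy.hybrid_fit
#' @return `glance()` returns a one-row model summary.
#' @export
glance.hybrid_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_trials = x$n_trials,
                 beta = x$beta, persev = x$persev,
                 convergence = x$convergence)
}

#' Tidy a psychometric fit
#'
#' @param x An `econ_psychometric`.
#' @param ... Unused.
#' @return One row per coefficient of the logistic choice model.
#' @export
tidy.econ_psychometric <- function(x, ...) {
  tibble::tibble(term = c("intercept", "log_offer_ratio"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.econ_psychometric
#' @export
glance.econ_psychometric <- function(x, ...) {
  tibble::tibble(relative_value = x$relative_value, n_trials = x$n_trials)
}

#' Tidy a population PCA
#'
#' @param x A `population_pca`.
#' @param ... Unused.
#' @return One row per component with its variance fraction.
#' @export
tidy.population_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_frac),
                 var_frac = x$var_frac,
                 cum_var_frac = x$cum_var_frac)
}

#' Tidy a value-selectivity taxonomy
#'
#' @param x A `value_taxonomy`.
#' @param ... Unused.
#' @return The per-category proportion table.
#' @export
tidy.value_taxonomy <- function(x, ...) x$proportions

#' @rdname tidy.value_taxonomy
#' @export
glance.value_taxonomy <- function(x, ...) {
  tibble::tibble(n_neurons = nrow(x$neurons), n_classified = x$n_classified,
                 n_categories = x$n_categories)
}

#' Tidy a session result
#'
#' @param x A `session_result`.
#' @param ... Unused.
#' @return The trial log tibble.
#' @export
tidy.session_result <- function(x, ...) x$log

#' @rdname tidy.session_result
#' @export
glance.session_result <- function(x, ...) {
  tibble::tibble(task = x$config$task, n_trials = nrow(x$log),
                 seed = x$seed,
                 reward_rate = if (nrow(x$log)) mean(x$log$reward) else NA_real_,
                 updates = x$readout$trial_index)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
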