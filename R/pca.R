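#' Condition-averaged time-resolved reservoir traces
#'
#' Presents each task condition's input schedule repeatedly (with fresh
#' initial states and noise per presentation) and averages the full rate
#' trajectories, yielding the condition-by-time-by-neuron data that the
#' population state-space analysis operates on. Reservoir activity does not
#' depend on the readout, so the traces characterize the state encoding of
#' the trained network directly.
#'
#' @param reservoir A [build_reservoir()] network.
#' @param schedules Named list of [trial_schedule()]s, one per condition.
#' @param n_reps Presentations averaged per condition.
#' @param seed Master seed (trial counters are allocated per presentation).
#' @param epoch `c(from, to)` ms to retain (default: the whole trial).
#' @return A named list of time x neuron mean-rate matrices, one per
#'   condition, with the retained times as attribute `"times"`.
#' @export
collect_condition_traces <- function(reservoir, schedules, n_reps = 20,
                                     seed = 1, epoch = NULL) {
  stopifnot(length(schedules) >= 1, !is.null(names(schedules)))
  counter <- 0L
  out <- purrr::map(schedules, function(sch) {
    acc <- NULL
    for (r in seq_len(n_reps)) {
      counter <<- counter + 1L
      tr <- integrate_trial(reservoir, sch, seed, trial = counter,
                            record_trace = TRUE)
      acc <- if (is.null(acc)) tr$rates else acc + tr$rates
    }
    acc / n_reps
  })
  times <- seq_len(ncol(schedules[[1]]$inputs)) * reservoir$params$dt
  if (!is.null(epoch)) {
    keep <- which(times > epoch[1] & times <= epoch[2])
    out <- purrr::map(out, function(m) m[keep, , drop = FALSE])
    times <- times[keep]
  }
  attr(out, "times") <- times
  out
}

#' The four reversal-task condition schedules
#'
#' @param cfg A [reversal_config()].
#' @return Named list of schedules for conditions AR, AN, BR, BN (previous
#'   choice x previous outcome).
#' @export
reversal_condition_schedules <- function(cfg = reversal_config()) {
  conds <- list(AR = c("A", 1), AN = c("A", 0), BR = c("B", 1), BN = c("B", 0))
  purrr::map(conds, function(cd)
    make_reversal_schedule(cd[1], as.integer(cd[2]), cfg))
}

#' The eight two-stage condition schedules
#'
#' @param cfg A [twostage_config()].
#' @return Named list of schedules for the conditions `A1B1R` ... `A2B2N`.
#' @export
twostage_condition_schedules <- function(cfg = twostage_config()) {
  conds <- twostage_conditions()
  out <- purrr::map(conds, function(cd) {
    make_twostage_schedule(substr(cd, 1, 2), substr(cd, 3, 4),
                           as.integer(substr(cd, 5, 5) == "R"), cfg)
  })
  names(out) <- conds
  out
}

#' Population PCA over condition-resolved activity
#'
#' Stacks the condition-averaged time-resolved rate matrices over
#' (condition, time) rows and computes principal components over the neuron
#' dimension (centered, unscaled). The cumulative variance captured by the
#' leading components measures how compactly the population separates the
#' task states.
#'
#' @param traces Named list of time x neuron matrices (one per condition),
#'   as from [collect_condition_traces()], or a single stacked matrix.
#' @param n_components Number of components to report trajectories for.
#' @param center If `TRUE` (default), compute components of the
#'   neuron-dimension covariance (variance about the mean activity pattern).
#'   If `FALSE`, compute them about the origin, so the reported fractions
#'   are shares of the total signal energy including the mean pattern — the
#'   convention under which the published state-space numbers for these
#'   networks are reproduced (see the methods vignette).
#' @return A `population_pca` object: `var_frac`, `cum_var_frac`, `rotation`
#'   (neuron loadings), and `projections` (per condition, time x component
#'   scores).
#' @export
population_pca <- function(traces, n_components = 3, center = TRUE) {
  if (is.matrix(traces)) traces <- list(all = traces)
  stacked <- do.call(rbind, traces)
  if (ncol(stacked) < n_components)
    stop("fewer neurons than requested components", call. = FALSE)
  pc <- stats::prcomp(stacked, center = center, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$rotation))
  rows <- vapply(traces, nrow, integer(1))
  stops <- cumsum(rows); starts <- stops - rows + 1L
  projections <- purrr::map2(starts, stops, function(a, b)
    pc$x[a:b, seq_len(k), drop = FALSE])
  names(projections) <- names(traces)
  structure(list(var_frac = var_frac, cum_var_frac = cumsum(var_frac),
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 projections = projections, n_components = k,
                 times = attr(traces, "times")),
            class = "population_pca")
}

#' @export
print.population_pca <- function(x, ...) {
  k <- x$n_components
  cat(sprintf("<population_pca> %d condition(s); first %d components carry %.1f%% of the variance\n",
              length(x$projections), k, 100 * x$cum_var_frac[k]))
  invisible(x)
}
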