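#' Plot an errors-to-criterion learning curve
#'
#' @param data An [errors_to_criterion()] table, or a list of them (e.g.
#'   one per seed or per condition); a list is combined with a `run` label.
#' @param ... Unused.
#' @return A ggplot object: errors to criterion per reversal block.
#' @export
plot_learning_curve <- function(data, ...) {
  if (!is.data.frame(data)) {
    nm <- names(data) %||% as.character(seq_along(data))
    data <- purrr::imap_dfr(data, function(d, i) dplyr::mutate(d, run = i))
  } else data$run <- "1"
  summ <- data |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(mean_errors = mean(.data$errors_to_criterion, na.rm = TRUE),
                     se = stats::sd(.data$errors_to_criterion, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$errors_to_criterion))),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$block, y = .data$mean_errors)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_errors - .data$se,
                                      ymax = .data$mean_errors + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Reversal block", y = "Errors to criterion") +
    ggplot2::theme_classic()
}

#' Plot population state-space trajectories
#'
#' Projects the condition trajectories onto the first two principal
#' components (the third is available via `components`).
#'
#' @param object A [population_pca()] result.
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.population_pca <- function(object, components = c(1, 2), ...) {
  df <- purrr::imap_dfr(object$projections, function(m, cond)
    tibble::tibble(condition = cond, step = seq_len(nrow(m)),
                   x = m[, components[1]], y = m[, components[2]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$condition)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = paste0("PC", components[1]),
                  y = paste0("PC", components[2])) +
    ggplot2::theme_classic()
}

#' Plot a stay-probability factorial table
#'
#' @param object A [stay_table()].
#' @param ... Unused.
#' @return A ggplot bar chart of the four conditional stay probabilities.
#' @export
autoplot.stay_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$state, y = .data$p_stay)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Previous-trial state", y = "P(stay)") +
    ggplot2::theme_classic()
}

#' Plot the economic choice pattern
#'
#' Empirical fraction of B choices per offer pair against the log offer
#' ratio, with the fitted psychometric curve.
#'
#' @param object An [econ_psychometric()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.econ_psychometric <- function(object, ...) {
  pat <- object$choice_pattern
  pat <- pat[pat$mag_A > 0 & pat$mag_B > 0, ]
  pat$log_ratio <- log(pat$mag_B / pat$mag_A)
  grid <- tibble::tibble(log_ratio = seq(min(pat$log_ratio),
                                         max(pat$log_ratio), length.out = 200))
  grid$frac_B <- stats::plogis(object$intercept + object$slope * grid$log_ratio)
  ggplot2::ggplot(pat, ggplot2::aes(x = .data$log_ratio, y = .data$frac_B)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "log(m_B / m_A)", y = "P(choose B)",
                  title = sprintf("relative value 1A = %.2fB",
                                  object$relative_value)) +
    ggplot2::theme_classic()
}

#' Plot readout weight evolution by selectivity group
#'
#' For each snapshot in a session's weight history, draws the mean
#' difference between the connections to the two outputs for each
#' selectivity group — the signature that combination-selective neurons
#' (e.g. AR, BR) carry the learned contingency while pure stimulus neurons
#' hover near zero.
#'
#' @param session A `session_result` with a recorded weight history.
#' @param labels Per-neuron selectivity labels ([classify_selectivity()]).
#' @param groups Which labels to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_weight_evolution <- function(session, labels, groups = NULL, ...) {
  if (!length(session$weight_history))
    stop("session has no recorded weight history", call. = FALSE)
  if (is.data.frame(labels)) labels <- labels$label
  groups <- groups %||% setdiff(unique(labels), "unselective")
  df <- purrr::imap_dfr(session$weight_history, function(W, i) {
    purrr::map_dfr(groups, function(gp) {
      sel <- labels == gp
      tibble::tibble(snapshot = i, group = gp,
                     wdiff = mean(W[sel, 1] - W[sel, 2]))
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$snapshot, y = .data$wdiff,
                                   colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Block", y = "Mean w(output 1) - w(output 2)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
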