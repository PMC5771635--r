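#' Classify neurons by preferred task condition
#'
#' For each neuron, the decision-time rates are compared across task
#' conditions with a one-way ANOVA; if the omnibus test is significant, the
#' condition with the largest mean rate is the candidate preferred
#' condition, and the neuron is labelled with it only if every pairwise
#' comparison (preferred vs. each other condition, Welch t-tests) survives
#' Bonferroni correction over the number of comparisons. Neurons that fail
#' the condition-level test can optionally be tested at the level of single
#' task factors (e.g. chosen option A vs. B, reward vs. none): a neuron
#' driven by input A in both AR and AN trials fails the 4-condition test but
#' is labelled `A` by the 2-level marginal test.
#'
#' @param rates Trials x neurons matrix of decision-time rates.
#' @param conditions Per-trial condition labels (character or factor).
#' @param alpha Significance level (0.05).
#' @param factors Optional named list of per-trial factor labels for the
#'   marginal fallback tests, e.g.
#'   `list(option = choices, outcome = c("N","R")[reward+1])`.
#' @return A tibble with one row per neuron: `neuron`, `label`
#'   (condition, factor level, or `"unselective"`), `level` (`"condition"`,
#'   `"factor"` or `"none"`), `p_omnibus`, `p_max_pairwise`.
#' @export
classify_selectivity <- function(rates, conditions, alpha = 0.05,
                                 factors = NULL) {
  conditions <- as.factor(conditions)
  if (nlevels(conditions) < 2)
    stop("need at least two conditions", call. = FALSE)
  if (any(table(conditions) < 2))
    stop("every condition needs at least two trials", call. = FALSE)
  if (nrow(rates) != length(conditions))
    stop("`rates` rows must match `conditions`", call. = FALSE)
  lv <- levels(conditions)
  idx <- lapply(lv, function(l) which(conditions == l))
  names(idx) <- lv
  n_cmp <- length(lv) - 1L
  out <- purrr::map_dfr(seq_len(ncol(rates)), function(j) {
    y <- rates[, j]
    if (stats::var(y) == 0)
      return(tibble::tibble(neuron = j, label = "unselective", level = "none",
                            p_omnibus = NA_real_, p_max_pairwise = NA_real_))
    p_omni <- tryCatch(
      stats::oneway.test(y ~ conditions, var.equal = TRUE)$p.value,
      error = function(e) NA_real_)
    label <- "unselective"; lev <- "none"; p_pair <- NA_real_
    if (is.finite(p_omni) && p_omni < alpha) {
      means <- vapply(idx, function(i) mean(y[i]), numeric(1))
      pref <- names(which.max(means))
      others <- setdiff(lv, pref)
      pv <- vapply(others, function(o) {
        tryCatch(stats::t.test(y[idx[[pref]]], y[idx[[o]]],
                               alternative = "greater")$p.value,
                 error = function(e) NA_real_)  # near-constant groups
      }, numeric(1))
      if (anyNA(pv)) pv[is.na(pv)] <- 1
      p_pair <- max(pv * n_cmp)  # Bonferroni-adjusted worst comparison
      if (p_pair < alpha) { label <- pref; lev <- "condition" }
    }
    if (lev == "none" && !is.null(factors)) {
      for (f in factors) {
        f <- as.factor(f)
        if (nlevels(f) != 2) next
        g1 <- y[f == levels(f)[1]]; g2 <- y[f == levels(f)[2]]
        p2 <- tryCatch(stats::t.test(g1, g2)$p.value * length(factors),
                       error = function(e) NA_real_)
        if (is.finite(p2) && p2 < alpha) {
          label <- levels(f)[which.max(c(mean(g1), mean(g2)))]
          lev <- "factor"
          break
        }
      }
    }
    tibble::tibble(neuron = j, label = label, level = lev,
                   p_omnibus = p_omni, p_max_pairwise = p_pair)
  })
  out
}

#' Selectivity categories of the two-stage task
#'
#' Groups the eight choice-by-intermediate-by-outcome conditions (`A1B1R`,
#' `A1B1N`, ..., `A2B2N`) into evidence categories. Category `XR` contains
#' the conditions in which event `X` co-occurs with reward or the
#' alternative of `X` co-occurs with non-reward — all the conditions that
#' provide evidence for associating `X` with reward. `XN` is the complement
#' pattern. Note the equivalences `A1R = A2N`, `A1N = A2R`, `B1R = B2N`,
#' `B1N = B2R`: each condition belongs to one A-side category (under two
#' names) and one B-side category.
#'
#' @param preferred A character vector of preferred conditions (each one of
#'   the 8).
#' @return A tibble with columns `condition` and `category` (one row per
#'   matching category name, four per condition).
#' @seealso [category_members()]
#' @export
group_category <- function(preferred) {
  conds <- twostage_conditions()
  bad <- setdiff(unique(preferred), conds)
  if (length(bad))
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cats <- twostage_categories()
  purrr::map_dfr(preferred, function(cond) {
    hit <- names(cats)[vapply(cats, function(m) cond %in% m, logical(1))]
    tibble::tibble(condition = cond, category = hit)
  })
}

#' The eight two-stage conditions
#' @keywords internal
twostage_conditions <- function() {
  as.vector(outer(outer(c("A1", "A2"), c("B1", "B2"), paste0),
                  c("R", "N"), paste0))
}

#' Members of a two-stage selectivity category
#'
#' @param name Category name: one of `A1R`, `A1N`, `A2R`, `A2N`, `B1R`,
#'   `B1N`, `B2R`, `B2N`.
#' @return Character vector of the four member conditions.
#' @export
category_members <- function(name) {
  cats <- twostage_categories()
  if (!name %in% names(cats))
    stop("unknown category: ", name, call. = FALSE)
  cats[[name]]
}

twostage_categories <- function() {
  conds <- twostage_conditions()
  has <- function(cond, ev) grepl(ev, cond, fixed = TRUE)
  alt <- c(A1 = "A2", A2 = "A1", B1 = "B2", B2 = "B1")
  out <- list()
  for (x in names(alt)) {
    rewarded_with <- conds[(has(conds, x) & endsWith(conds, "R")) |
                           (has(conds, alt[[x]]) & endsWith(conds, "N"))]
    out[[paste0(x, "R")]] <- rewarded_with
    out[[paste0(x, "N")]] <- setdiff(conds, rewarded_with)
  }
  out
}
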