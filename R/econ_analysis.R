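#' Choice psychometrics and relative value estimate
#'
#' Fits the logistic choice model `p(choose B) = sigmoid(a + b * log(m_B /
#' m_A))` on non-forced trials (both offers positive). The indifference
#' point `exp(-a / b)` estimates the relative value of juice A in units of
#' juice B — the quantity set to `gamma` in the generating task. Forced
#' trials and the per-offer-pair empirical choice fractions are returned
#' for plotting.
#'
#' @param log An economic-choice session log (`mag_A`, `mag_B`, `choice`).
#' @return An `econ_psychometric` object: `relative_value`, `intercept`,
#'   `slope`, `n_trials`, and `choice_pattern` (per offer pair: count and
#'   fraction of B choices).
#' @export
econ_psychometric <- function(log) {
  need <- c("mag_A", "mag_B", "choice")
  if (!all(need %in% names(log)))
    stop("not an economic-choice log", call. = FALSE)
  free <- log$mag_A > 0 & log$mag_B > 0
  if (sum(free) < 10)
    stop("too few non-forced trials for a psychometric fit", call. = FALSE)
  d <- log[free, ]
  x <- log(d$mag_B / d$mag_A)
  y <- as.integer(d$choice == "B")
  if (length(unique(y)) < 2)
    stop("degenerate choice pattern: only one option ever chosen",
         call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  a <- stats::coef(fit)[[1]]; b <- stats::coef(fit)[[2]]
  pattern <- log |>
    dplyr::group_by(.data$mag_A, .data$mag_B) |>
    dplyr::summarise(n = dplyr::n(),
                     frac_B = mean(.data$choice == "B"), .groups = "drop")
  structure(list(relative_value = exp(-a / b), intercept = a, slope = b,
                 n_trials = sum(free), choice_pattern = pattern,
                 model = fit),
            class = "econ_psychometric")
}

#' @export
print.econ_psychometric <- function(x, ...) {
  cat(sprintf(
    "<econ_psychometric> relative value 1A = %.2fB (slope %.2f, n = %d non-forced trials)\n",
    x$relative_value, x$slope, x$n_trials))
  invisible(x)
}

#' Trial-by-trial value variables
#'
#' Builds the ten value variables of the selectivity taxonomy from an
#' economic-choice log: total value, chosen value, other value, value
#' difference (chosen - other), value ratio (other / chosen; undefined when
#' the chosen value is 0), offer value A, offer value B, chosen juice
#' (indicator of choosing A), value A chosen and value B chosen (the offer
#' value on the trials where that juice was chosen). All values are in
#' units of juice B (`value A = gamma * mag_A`).
#'
#' @param log An economic-choice session log.
#' @param gamma Relative value of juice A used by the environment.
#' @return A tibble of per-trial variables; entries are `NA` on trials where
#'   a variable is undefined (those trials are excluded from that variable's
#'   regression).
#' @export
value_variables <- function(log, gamma = 2) {
  vA <- gamma * log$mag_A
  vB <- log$mag_B
  chosen <- ifelse(log$choice == "A", vA, vB)
  other <- ifelse(log$choice == "A", vB, vA)
  tibble::tibble(
    total_value = vA + vB,
    chosen_value = chosen,
    other_value = other,
    value_difference = chosen - other,
    value_ratio = ifelse(chosen > 0, other / chosen, NA_real_),
    offer_value_A = vA,
    offer_value_B = vB,
    chosen_juice = as.numeric(log$choice == "A"),
    value_A_chosen = ifelse(log$choice == "A", vA, NA_real_),
    value_B_chosen = ifelse(log$choice == "B", vB, NA_real_))
}

#' Value-selectivity taxonomy
#'
#' Regresses each neuron's post-offer firing rate on each of the ten value
#' variables (simple linear regression per variable). A variable explains a
#' neuron if its slope differs from zero at `alpha` after Bonferroni
#' correction across the ten variables; a neuron is assigned to the
#' explaining variable with the highest R-squared. Constant variables are
#' skipped with a warning.
#'
#' @param rates Trials x neurons matrix of rates averaged over the
#'   post-offer window (0-500 ms after stimulus onset).
#' @param vars A [value_variables()] tibble (same trial count).
#' @param alpha Significance level before Bonferroni correction.
#' @return A `value_taxonomy` list: `neurons` (tibble with `neuron`,
#'   `category`, `r_squared`, `p_value`) and `proportions` (tibble with
#'   per-category counts and proportions over classified neurons).
#' @export
value_regression_taxonomy <- function(rates, vars, alpha = 0.05) {
  if (nrow(rates) != nrow(vars))
    stop("`rates` and `vars` must cover the same trials", call. = FALSE)
  if (nrow(rates) < 100)
    stop("need at least 100 analysis trials", call. = FALSE)
  keep <- vapply(vars, function(v) stats::var(v, na.rm = TRUE) > 0, logical(1))
  if (any(!keep))
    warning("skipping constant variable(s): ",
            paste(names(vars)[!keep], collapse = ", "))
  vnames <- names(vars)[keep]
  m <- length(names(vars))  # Bonferroni over the full taxonomy size
  n_neur <- ncol(rates)
  p_mat <- matrix(NA_real_, n_neur, length(vnames),
                  dimnames = list(NULL, vnames))
  r2_mat <- p_mat
  for (v in vnames) {
    x <- vars[[v]]
    ok <- !is.na(x)
    res <- slope_tests(x[ok], rates[ok, , drop = FALSE])
    p_mat[, v] <- res$p
    r2_mat[, v] <- res$r2
  }
  adj <- pmin(p_mat * m, 1)
  pick <- vapply(seq_len(n_neur), function(i) {
    sig <- which(adj[i, ] < alpha)
    if (!length(sig)) return(NA_integer_)
    sig[which.max(r2_mat[i, sig])]
  }, integer(1))
  neurons <- tibble::tibble(
    neuron = seq_len(n_neur),
    category = ifelse(is.na(pick), NA_character_, vnames[pick]),
    r_squared = ifelse(is.na(pick), NA_real_,
                       r2_mat[cbind(seq_len(n_neur), pick)]),
    p_value = ifelse(is.na(pick), NA_real_,
                     adj[cbind(seq_len(n_neur), pick)]))
  classified <- neurons[!is.na(neurons$category), ]
  proportions <- tibble::tibble(category = names(vars)) |>
    dplyr::mutate(n = vapply(.data$category,
                             function(cc) sum(classified$category == cc),
                             numeric(1)),
                  proportion = if (nrow(classified))
                                 .data$n / nrow(classified) else NA_real_)
  structure(list(neurons = neurons, proportions = proportions,
                 n_classified = nrow(classified),
                 n_categories = sum(proportions$n > 0)),
            class = "value_taxonomy")
}

#' @export
print.value_taxonomy <- function(x, ...) {
  cat(sprintf(
    "<value_taxonomy> %d of %d neurons classified across %d of %d categories\n",
    x$n_classified, nrow(x$neurons), x$n_categories, nrow(x$proportions)))
  invisible(x)
}

# vectorized simple-regression slope t-tests of many responses on one
# regressor; algebraically identical to lm(rate ~ x) per neuron (checked in
# the test suite)
slope_tests <- function(x, Y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) return(list(p = rep(NA_real_, ncol(Y)),
                            r2 = rep(NA_real_, ncol(Y))))
  Yc <- sweep(Y, 2, colMeans(Y))
  sxy <- drop(crossprod(xc, Yc))
  syy <- colSums(Yc^2)
  b <- sxy / sxx
  sse <- pmax(syy - b * sxy, 0)
  df <- n - 2
  se <- sqrt(sse / df / sxx)
  tstat <- ifelse(se > 0, b / se, Inf * sign(b))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[syy == 0] <- NA_real_  # constant neuron: no variance to explain
  r2 <- ifelse(syy > 0, (sxy^2) / (sxx * syy), NA_real_)
  list(p = p, r2 = r2)
}
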