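#' Stay-probability factorial table
#'
#' Classifies every two-stage trial by whether its intermediate outcome was
#' the common consequence of the choice and by its reward — common-rewarded
#' (CR), common-unrewarded (CN), rare-rewarded (RR), rare-unrewarded (RN) —
#' and tabulates the probability of repeating the choice on the next trial
#' in each cell. A structure-aware agent stays after CR and RN and switches
#' after CN and RR; a structure-agnostic one only cares about reward.
#'
#' @param log A two-stage session log (needs `choice`, `common`, `reward`).
#' @return A `stay_table` tibble: `state`, `n`, `n_stay`, `p_stay`.
#' @export
stay_table <- function(log) {
  need <- c("choice", "common", "reward")
  if (!all(need %in% names(log)))
    stop("not a two-stage log: need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  n <- nrow(log)
  if (n < 2) stop("need at least two trials", call. = FALSE)
  state <- paste0(ifelse(log$common, "C", "R"),
                  ifelse(log$reward == 1, "R", "N"))[-n]
  stay <- (log$choice[-1] == log$choice[-n])
  out <- tibble::tibble(state = factor(state, c("CR", "CN", "RR", "RN"))) |>
    dplyr::mutate(stay = stay) |>
    dplyr::group_by(.data$state, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), n_stay = sum(.data$stay),
                     p_stay = ifelse(dplyr::n() > 0,
                                     sum(.data$stay) / dplyr::n(), NA_real_),
                     .groups = "drop")
  class(out) <- c("stay_table", class(out))
  out
}

#' Task-structure index
#'
#' `(p(stay|CR) + p(stay|RN) - p(stay|CN) - p(stay|RR)) / (sum of the four)`:
#' a normalized contrast in \[-1, 1\] measuring how much the transition
#' structure (rather than reward alone) drives choice repetition. 0 for a
#' purely reward-driven or random agent, 1 for perfect structure use.
#'
#' @param table A [stay_table()] (or a named numeric with entries CR, CN,
#'   RR, RN).
#' @return The scalar index.
#' @export
ts_index <- function(table) {
  p <- if (inherits(table, "data.frame")) {
    stats::setNames(table$p_stay, as.character(table$state))
  } else table
  if (!all(c("CR", "CN", "RR", "RN") %in% names(p)))
    stop("need stay probabilities for all four states", call. = FALSE)
  denom <- p[["CR"]] + p[["RN"]] + p[["CN"]] + p[["RR"]]
  if (!is.finite(denom) || denom == 0)
    stop("task-structure index undefined: stay probabilities sum to zero",
         call. = FALSE)
  (p[["CR"]] + p[["RN"]] - p[["CN"]] - p[["RR"]]) / denom
}

#' Log-likelihood of the hybrid model-free / model-based learner
#'
#' Evaluates the sequential likelihood of a two-stage choice sequence under
#' the hybrid learner: the model-free values of the observed intermediate
#' state and the chosen first-stage option are updated by a delta rule with
#' learning rate `alpha1` and eligibility `lambda`; the model-based system
#' updates the observed intermediate state with rate `alpha2` and
#' recomputes both first-stage values through the true transition matrix;
#' the net value is `w * V_MB + (1 - w) * V_MF` and choices follow a
#' softmax with fixed inverse temperature `beta` and perseveration `p`.
#'
#' @param params Numeric `c(alpha1, alpha2, lambda, w)`, each in \[0, 1\].
#' @param log A two-stage session log (`choice`, `intermediate`, `reward`).
#' @param common_prob The task's common-transition probability.
#' @param beta Fixed softmax inverse temperature (2, matching the generating
#'   behaviour).
#' @param persev Fixed perseveration weight (0; the network state is reset
#'   every trial).
#' @param eps Floor applied to choice probabilities before taking logs.
#' @param literal_mf If `TRUE`, use the nested form of the first-stage
#'   model-free update in which the eligibility term propagates the value
#'   *change* `alpha1 * (r - V(B))` instead of the prediction error
#'   `r - V(B)`. Under that form first-stage model-free learning is second
#'   order in `alpha1`, which cripples the model-free half of the mixture
#'   and biases the fitted `w` upward; the default follows the first-order
#'   eligibility rule of the model this fit simplifies.
#' @return The summed log-likelihood (<= 0).
#' @export
hybrid_loglik <- function(params, log, common_prob = 0.8, beta = 2,
                          persev = 0, eps = 1e-12, literal_mf = FALSE) {
  if (length(params) != 4 || any(params < 0) || any(params > 1))
    stop("`params` must be c(alpha1, alpha2, lambda, w) in [0,1]",
         call. = FALSE)
  .hybrid_loglik_cpp(params[1], params[2], params[3], params[4],
                     match(log$choice, c("A1", "A2")),
                     match(log$intermediate, c("B1", "B2")),
                     as.numeric(log$reward), common_prob, beta, persev, eps,
                     isTRUE(literal_mf))
}

#' Fit the hybrid learner by maximum likelihood
#'
#' Maximizes [hybrid_loglik()] over `(alpha1, alpha2, lambda, w)` in
#' \[0,1\]^4 with bounded quasi-Newton optimization from multiple random
#' restarts. The weight `w` measures reliance on the task's transition
#' structure: 0 is fully task-agnostic, 1 fully task-aware.
#'
#' @param log A two-stage session log.
#' @param restarts Number of random restarts (20).
#' @param seed Seed for the restart draws.
#' @inheritParams hybrid_loglik
#' @return A `hybrid_fit`: `alpha1`, `alpha2`, `lambda`, `w`, `loglik`,
#'   `n_trials`, `convergence`.
#' @export
fit_hybrid <- function(log, restarts = 20, seed = 1, common_prob = 0.8,
                       beta = 2, persev = 0, literal_mf = FALSE) {
  if (nrow(log) < 100)
    stop("need at least 100 trials to fit the hybrid model", call. = FALSE)
  starts <- with_seed(seed, matrix(stats::runif(restarts * 4), restarts, 4))
  nll <- function(par) -hybrid_loglik(par, log, common_prob, beta, persev,
                                      literal_mf = literal_mf)
  best <- NULL
  for (i in seq_len(restarts)) {
    fit <- tryCatch(
      stats::optim(starts[i, ], nll, method = "L-BFGS-B",
                   lower = rep(1e-9, 4), upper = rep(1 - 1e-9, 4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("hybrid fit failed on all restarts", call. = FALSE)
  structure(list(alpha1 = best$par[1], alpha2 = best$par[2],
                 lambda = best$par[3], w = best$par[4],
                 loglik = -best$value, n_trials = nrow(log),
                 beta = beta, persev = persev,
                 convergence = best$convergence),
            class = "hybrid_fit")
}

#' @export
print.hybrid_fit <- function(x, ...) {
  cat(sprintf(
    "<hybrid_fit> w = %.3f, alpha1 = %.3f, alpha2 = %.3f, lambda = %.3f (logLik %.1f, n = %d)\n",
    x$w, x$alpha1, x$alpha2, x$lambda, x$loglik, x$n_trials))
  invisible(x)
}

#' Simulate the hybrid learner
#'
#' Generates two-stage behaviour from the hybrid model itself (the
#' generative counterpart of [fit_hybrid()], used for parameter-recovery
#' checks).
#'
#' @param params `c(alpha1, alpha2, lambda, w)`.
#' @param n_trials Number of trials.
#' @param cfg A [twostage_config()].
#' @param seed Seed.
#' @inheritParams hybrid_loglik
#' @return A log tibble compatible with [fit_hybrid()] and [stay_table()].
#' @export
simulate_hybrid_agent <- function(params, n_trials, cfg = twostage_config(),
                                  seed = 1, beta = 2, persev = 0,
                                  literal_mf = FALSE) {
  vmf_a <- c(0, 0); vmf_b <- c(0, 0); vmb_a <- c(0, 0); vmb_b <- c(0, 0)
  P <- matrix(c(cfg$common_prob, 1 - cfg$common_prob,
                1 - cfg$common_prob, cfg$common_prob), 2, byrow = TRUE)
  choice <- integer(n_trials); interm <- integer(n_trials)
  reward <- integer(n_trials); common <- logical(n_trials)
  prev <- 0L
  for (t in seq_len(n_trials)) {
    vnet <- params[4] * vmb_a + (1 - params[4]) * vmf_a
    u_val <- beta * vnet + persev * (seq_len(2) == prev)
    pr <- exp(u_val - max(u_val)); pr <- pr / sum(pr)
    u <- stream_uniforms(seed, STREAM_CHOICE, t, 1)
    a <- 1L + (u >= pr[1])
    st <- twostage_step(t, c("A1", "A2")[a], cfg,
                        stream_uniforms(seed, STREAM_ENV, t, 2))
    b <- match(st$intermediate, c("B1", "B2"))
    r <- st$reward
    dvb <- r - vmf_b[b]
    vmf_b[b] <- vmf_b[b] + params[1] * dvb
    vmf_a[a] <- vmf_a[a] + params[1] * params[3] *
      (if (literal_mf) params[1] * dvb else dvb)
    vmb_b[b] <- vmb_b[b] + params[2] * (r - vmb_b[b])
    vmb_a <- drop(P %*% vmb_b)
    choice[t] <- a; interm[t] <- b; reward[t] <- r; common[t] <- st$common
    prev <- a
  }
  tibble::tibble(trial = seq_len(n_trials),
                 block = (seq_len(n_trials) - 1L) %/% cfg$block_length + 1L,
                 choice = c("A1", "A2")[choice],
                 intermediate = c("B1", "B2")[interm],
                 common = common, reward = reward)
}

#' Lagged-state logistic regression
#'
#' Estimates how the four trial states (2 intermediate outcomes x 2 reward
#' outcomes, coded common/rare x rewarded/unrewarded) of each of the last
#' `lags` trials influence the current choice. Each regressor is the state
#' indicator at that lag signed by the choice taken then (+1 for `A1`), so
#' a positive coefficient means the state favours repeating that choice.
#'
#' @param log A two-stage session log.
#' @param lags Number of past trials (10).
#' @return A tibble with `state`, `lag`, `estimate`, `std_error`, `p_value`.
#' @export
lagged_state_regression <- function(log, lags = 10) {
  n <- nrow(log)
  if (n <= lags * 4)
    stop("log too short for ", lags, " lags", call. = FALSE)
  states <- c("CR", "CN", "RR", "RN")
  st <- paste0(ifelse(log$common, "C", "R"),
               ifelse(log$reward == 1, "R", "N"))
  sgn <- ifelse(log$choice == "A1", 1, -1)
  rows <- (lags + 1L):n
  X <- matrix(0, length(rows), lags * 4)
  cn <- character(lags * 4)
  k <- 0L
  for (lag in seq_len(lags)) {
    for (s in states) {
      k <- k + 1L
      X[, k] <- sgn[rows - lag] * (st[rows - lag] == s)
      cn[k] <- paste0(s, "_lag", lag)
    }
  }
  colnames(X) <- cn
  y <- as.integer(log$choice[rows] == "A1")
  fit <- fit_logistic(y, X)
  tibble::tibble(state = rep(states, lags),
                 lag = rep(seq_len(lags), each = 4),
                 estimate = fit$coef[cn], std_error = fit$se[cn],
                 p_value = fit$p[cn])
}

#' Factor logistic regression of two-stage choice
#'
#' Regresses the current choice on five candidate influences from the last
#' trial and the block: `Correct` (+1 when `A1` is currently the better
#' option), `Reward` (previous choice signed by rewarded/unrewarded),
#' `Stay` (previous choice), `Transition` (previous choice signed by
#' common/rare), and `TransXOut` (previous choice signed by the
#' transition-outcome interaction — the signature of structure use).
#'
#' @param log A two-stage session log (needs block annotations).
#' @return A tibble with `factor`, `estimate`, `std_error`, `p_value`.
#' @export
factor_regression <- function(log) {
  need <- c("choice", "common", "reward", "good_outcome")
  if (!all(need %in% names(log)))
    stop("need a two-stage log with block annotations", call. = FALSE)
  n <- nrow(log)
  prev <- ifelse(log$choice == "A1", 1, -1)[-n]
  r <- (2 * log$reward - 1)[-n]
  tr <- (2 * as.integer(log$common) - 1)[-n]
  # the better option is the one whose common outcome is currently good
  better <- ifelse(log$good_outcome == "B1", 1, -1)[-1]
  X <- cbind(Correct = better, Reward = prev * r, Stay = prev,
             Transition = prev * tr, TransXOut = prev * r * tr)
  y <- as.integer(log$choice[-1] == "A1")
  fit <- fit_logistic(y, X)
  tibble::tibble(factor = colnames(X), estimate = fit$coef[colnames(X)],
                 std_error = fit$se[colnames(X)],
                 p_value = fit$p[colnames(X)])
}

# logistic fit with an intercept; falls back to a weak ridge penalty under
# separation
fit_logistic <- function(y, X) {
  df <- data.frame(y = y, X, check.names = FALSE)
  form <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)),
                                               collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = df, family = stats::binomial()),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (warned && !fit$converged) {
    warning("separation in logistic regression; refitting with a weak L2 penalty")
    # ridge-penalized refit keeps the coefficients finite
    pen <- glm_ridge(y, X, lambda = 1e-3)
    return(pen)
  }
  sm <- summary(fit)$coefficients
  rn <- rownames(sm)
  rn <- gsub("`", "", rn)
  list(coef = stats::setNames(sm[, 1], rn), se = stats::setNames(sm[, 2], rn),
       p = stats::setNames(sm[, 4], rn))
}

glm_ridge <- function(y, X, lambda = 1e-3) {
  Xi <- cbind(`(Intercept)` = 1, X)
  b <- rep(0, ncol(Xi))
  for (it in 1:100) {
    eta <- drop(Xi %*% b)
    mu <- 1 / (1 + exp(-eta))
    wt <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wt
    H <- crossprod(Xi, Xi * wt) + diag(lambda, ncol(Xi))
    bn <- solve(H, crossprod(Xi, wt * z))
    if (max(abs(bn - b)) < 1e-10) { b <- bn; break }
    b <- bn
  }
  se <- sqrt(diag(solve(H)))
  zval <- drop(b) / se
  rn <- colnames(Xi)
  list(coef = stats::setNames(drop(b), rn), se = stats::setNames(se, rn),
       p = stats::setNames(2 * stats::pnorm(-abs(zval)), rn))
}
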