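mk_ts_log <- function(choice, intermediate, reward, block_length = 50) {
  n <- length(choice)
  common <- (choice == "A1" & intermediate == "B1") |
            (choice == "A2" & intermediate == "B2")
  tibble::tibble(trial = seq_len(n),
                 block = (seq_len(n) - 1L) %/% block_length + 1L,
                 good_outcome = ifelse(((seq_len(n) - 1L) %/% block_length) %% 2L == 0L,
                                       "B1", "B2"),
                 choice = choice, intermediate = intermediate,
                 common = common, reward = reward)
}

test_that("stay probabilities reflect the generating policy", {
  # an agent that always repeats
  log <- mk_ts_log(rep("A1", 60), rep(c("B1", "B2"), 30), rep(0:1, 30))
  st <- stay_table(log)
  expect_true(all(st$p_stay[st$n > 0] == 1))
  # win-stay / lose-shift, with outcomes arranged to visit all four states
  set.seed(8)
  n <- 400
  interm <- character(n); reward <- integer(n); choice <- character(n)
  choice[1] <- "A1"
  cfg <- twostage_config()
  for (t in 1:n) {
    st_t <- twostage_step(t, choice[t], cfg, stream_uniforms(5, 4, t, 2))
    interm[t] <- st_t$intermediate; reward[t] <- st_t$reward
    if (t < n) choice[t + 1] <- if (reward[t] == 1) choice[t]
               else setdiff(c("A1", "A2"), choice[t])
  }
  stw <- stay_table(mk_ts_log(choice, interm, reward))
  expect_equal(stw$p_stay[stw$state == "CR"], 1)
  expect_equal(stw$p_stay[stw$state == "RR"], 1)
  expect_equal(stw$p_stay[stw$state == "CN"], 0)
  expect_equal(stw$p_stay[stw$state == "RN"], 0)
  # and a WSLS agent has a task-structure index of exactly 0
  expect_equal(ts_index(stw), 0)
})

test_that("rare transitions are classified as rare", {
  log <- mk_ts_log(c("A1", "A1"), c("B2", "B1"), c(1L, 0L))
  expect_equal(log$common, c(FALSE, TRUE))
  st <- stay_table(log)
  expect_equal(sum(st$n), 1)  # one transition, from the rare-rewarded state
  expect_equal(st$n[st$state == "RR"], 1L)
})

test_that("the task-structure index matches its closed form", {
  p <- c(CR = 1, CN = 0, RR = 0, RN = 1)
  expect_equal(ts_index(p), 1)
  expect_equal(ts_index(c(CR = .5, CN = .5, RR = .5, RN = .5)), 0)
  expect_equal(ts_index(c(CR = .8, CN = .4, RR = .4, RN = .8)), 1 / 3,
               tolerance = 1e-9)
  expect_equal(ts_index(c(CR = .8, CN = .4, RR = .4, RN = .8)), 0.333333,
               tolerance = 1e-5)
  expect_error(ts_index(c(CR = 0, CN = 0, RR = 0, RN = 0)), "undefined")
  # bounds over random tables
  for (k in 1:50) {
    p <- stream_uniforms(13, 4, k, 4)
    names(p) <- c("CR", "CN", "RR", "RN")
    expect_gte(ts_index(p), -1)
    expect_lte(ts_index(p), 1)
  }
})

test_that("hybrid log-likelihood matches a hand-stepped evaluation", {
  log <- mk_ts_log(c("A1", "A1", "A2"), c("B1", "B2", "B2"), c(1L, 0L, 1L))
  a1 <- 0.3; a2 <- 0.2; lam <- 0.5; w <- 0.6; beta <- 2; P <- 0.8
  # independent sequential evaluation of the update equations
  step <- function(literal) {
    vmf_a <- c(0, 0); vmf_b <- c(0, 0); vmb_a <- c(0, 0); vmb_b <- c(0, 0)
    ll <- 0
    for (t in 1:3) {
      a <- match(log$choice[t], c("A1", "A2"))
      b <- match(log$intermediate[t], c("B1", "B2"))
      r <- log$reward[t]
      vnet <- w * vmb_a + (1 - w) * vmf_a
      pr <- exp(beta * vnet) / sum(exp(beta * vnet))
      ll <- ll + log(pr[a])
      delta <- r - vmf_b[b]
      vmf_b[b] <- vmf_b[b] + a1 * delta
      # eligibility propagates the prediction error; the nested "literal"
      # variant propagates the value change a1 * delta instead
      vmf_a[a] <- vmf_a[a] + a1 * lam * (if (literal) a1 * delta else delta)
      vmb_b[b] <- vmb_b[b] + a2 * (r - vmb_b[b])
      vmb_a[1] <- P * vmb_b[1] + (1 - P) * vmb_b[2]
      vmb_a[2] <- (1 - P) * vmb_b[1] + P * vmb_b[2]
    }
    ll
  }
  expect_equal(hybrid_loglik(c(a1, a2, lam, w), log), step(FALSE),
               tolerance = 1e-10)
  expect_equal(hybrid_loglik(c(a1, a2, lam, w), log, literal_mf = TRUE),
               step(TRUE), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(step(TRUE), step(FALSE))))
})

test_that("single update equations give the printed values", {
  # model-based propagation: P = 0.8/0.2, V(B1) = 1, V(B2) = 0 -> V(A1) = 0.8
  log <- mk_ts_log(c("A1", "A1"), c("B1", "B1"), c(1L, 1L))
  # with alpha2 = 1 the first trial sets V_MB(B1) = 1, so trial 2's
  # net value for A1 is w * 0.8; with w = 1, beta = 2:
  ll <- hybrid_loglik(c(0, 1, 0, 1), log)
  # trial 1: p = 0.5; trial 2: p(A1) = 1/(1 + exp(-2*(0.8 - 0.2)))
  p2 <- 1 / (1 + exp(-2 * (0.8 - 0.2)))
  expect_equal(ll, log(0.5) + log(p2), tolerance = 1e-12)
  # delta rule: V = 0.5, r = 1, alpha = 0.1 -> 0.55
  expect_equal(0.5 + 0.1 * (1 - 0.5), 0.55)
  # softmax: V_net = (0.8, 0.2), beta = 2 -> p(A1) = 1/(1 + e^{-1.2})
  expect_equal(1 / (1 + exp(-1.2)), 0.768525, tolerance = 1e-6)
})

test_that("hybrid fitting recovers the generating weight", {
  gen <- c(0.3, 0.3, 0.5, 0.9)
  log <- simulate_hybrid_agent(gen, 2000, seed = 21)
  fit <- fit_hybrid(log, restarts = 10, seed = 1)
  expect_lt(abs(fit$w - 0.9), 0.15)
  # the optimum is at least as good as the generator's own likelihood
  expect_gte(fit$loglik, hybrid_loglik(gen, log) - 1e-6)
  # a purely model-free generator is recovered near the boundary
  log0 <- simulate_hybrid_agent(c(0.3, 0.3, 0.5, 0), 2000, seed = 22)
  fit0 <- fit_hybrid(log0, restarts = 10, seed = 1)
  expect_lt(fit0$w, 0.2)
})

test_that("hybrid fit input validation", {
  log <- simulate_hybrid_agent(c(.2, .2, .5, .5), 50, seed = 1)
  expect_error(fit_hybrid(log), "100")
  expect_error(hybrid_loglik(c(2, 0, 0, 0), log), "0,1")
})

test_that("lagged regression localizes the influence to the right lag", {
  # an agent that tends (80%) to repeat the choice made two trials back iff
  # that trial was rewarded, and to flip it otherwise (lag-2-only
  # dependence, stochastic so the regression stays well-conditioned)
  n <- 2000
  cfg <- twostage_config()
  choice <- character(n); interm <- character(n); reward <- integer(n)
  choice[1:2] <- c("A1", "A2")
  noise <- stream_uniforms(31, 3, 1, n)
  for (t in 1:n) {
    st <- twostage_step(t, choice[t], cfg, stream_uniforms(31, 4, t, 2))
    interm[t] <- st$intermediate; reward[t] <- st$reward
    if (t >= 2 && t < n) {
      ruled <- if (reward[t - 1] == 1) choice[t - 1]
               else setdiff(c("A1", "A2"), choice[t - 1])
      choice[t + 1] <- if (noise[t] < 0.8) ruled
                       else setdiff(c("A1", "A2"), ruled)
    }
  }
  out <- lagged_state_regression(mk_ts_log(choice, interm, reward), lags = 3)
  # rewarded states two trials back push toward repeating that choice,
  # unrewarded ones toward flipping it
  lag2 <- out[out$lag == 2, ]
  expect_true(all(lag2$estimate[lag2$state %in% c("CR", "RR")] > 0.5))
  expect_true(all(lag2$estimate[lag2$state %in% c("CN", "RN")] < -0.5))
  expect_true(all(lag2$p_value < 1e-4))
  # lag-3 carries no comparable signal
  lag3 <- out[out$lag == 3, ]
  expect_true(all(abs(lag3$estimate) < 0.5))
})

test_that("random behaviour yields null regressions", {
  set.seed(10)
  n <- 800
  cfg <- twostage_config()
  choice <- c("A1", "A2")[1 + (stream_uniforms(17, 3, 1, n) > 0.5)]
  interm <- character(n); reward <- integer(n)
  for (t in 1:n) {
    st <- twostage_step(t, choice[t], cfg, stream_uniforms(17, 4, t, 2))
    interm[t] <- st$intermediate; reward[t] <- st$reward
  }
  log <- mk_ts_log(choice, interm, reward)
  lag <- lagged_state_regression(log, lags = 2)
  expect_true(all(abs(lag$estimate) < 0.8))
  expect_lt(mean(lag$p_value < 0.05), 0.3)
  fac <- factor_regression(log)
  expect_true(all(abs(fac$estimate) < 0.5))
})

test_that("factor regression separates perseveration from structure use", {
  set.seed(11)
  n <- 1200
  cfg <- twostage_config()
  # pure perseveration with occasional random flips
  choice <- character(n); interm <- character(n); reward <- integer(n)
  choice[1] <- "A1"
  flips <- stream_uniforms(19, 3, 1, n)
  for (t in 1:n) {
    st <- twostage_step(t, choice[t], cfg, stream_uniforms(19, 4, t, 2))
    interm[t] <- st$intermediate; reward[t] <- st$reward
    if (t < n) choice[t + 1] <- if (flips[t] < 0.85) choice[t]
               else setdiff(c("A1", "A2"), choice[t])
  }
  out <- factor_regression(mk_ts_log(choice, interm, reward))
  stay <- out[out$factor == "Stay", ]
  txo <- out[out$factor == "TransXOut", ]
  expect_gt(stay$estimate, 1)
  expect_lt(stay$p_value, 1e-6)
  expect_lt(abs(txo$estimate), 0.5)
})
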