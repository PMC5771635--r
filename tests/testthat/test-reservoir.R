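test_that("recurrent connectivity matches the target density", {
  params <- reservoir_params(N = 500, p = 0.1)
  res <- build_reservoir(params, num_inputs = 3, seed = 1)
  nnz <- length(res$csr$values)
  # binomial 99% CI around p * N^2 = 25,000
  expected <- 0.1 * 500^2
  half <- qnorm(0.995) * sqrt(500^2 * 0.1 * 0.9)
  expect_gt(nnz, expected - half)
  expect_lt(nnz, expected + half)
  # nonzero weight variance close to 1/(p N)
  expect_equal(var(res$csr$values), 1 / (0.1 * 500), tolerance = 0.05)
})

test_that("zero-variance input weights give an all-zero projection", {
  res <- build_reservoir(reservoir_params(N = 30, p_IR = 1, g_IR = 0),
                         num_inputs = 2, seed = 7)
  expect_true(all(res$W_in == 0))
})

test_that("reservoir construction is a pure function of its seed", {
  a <- tiny_reservoir(seed = 11)
  b <- tiny_reservoir(seed = 11)
  expect_identical(a$W_rec, b$W_rec)
  expect_identical(a$W_in, b$W_in)
  c <- tiny_reservoir(seed = 12)
  expect_false(identical(a$W_rec, c$W_rec))
})

test_that("double-gain sampling scales the weights by g", {
  a <- build_reservoir(reservoir_params(N = 200, g = 2), 2, seed = 3)
  b <- build_reservoir(reservoir_params(N = 200, g = 2, double_gain = TRUE),
                       2, seed = 3)
  expect_equal(b$csr$values, 2 * a$csr$values)
})

test_that("invalid parameters are rejected by name", {
  expect_error(reservoir_params(N = 0), "N")
  expect_error(reservoir_params(tau = -1), "tau")
  expect_error(reservoir_params(dt = 200, tau = 100), "dt")
  expect_error(build_reservoir(reservoir_params(), 0, seed = 1), "num_inputs")
})

test_that("rate transfer matches hand-evaluated values and is well-behaved", {
  expect_equal(rate_transfer(0), 0.1)
  expect_equal(rate_transfer(-0.1), 0.1 + 0.1 * tanh(-1), tolerance = 1e-12)
  expect_equal(rate_transfer(-0.1), 0.023840, tolerance = 1e-4)
  expect_equal(rate_transfer(0.45), 0.1 + 0.9 * tanh(0.5), tolerance = 1e-12)
  expect_equal(rate_transfer(0.45), 0.515905, tolerance = 1e-4)
  # continuity at 0, monotonicity, limits
  xs <- seq(-30, 30, by = 0.01)
  ys <- rate_transfer(xs)
  expect_true(all(diff(ys) >= 0))
  expect_true(all(ys >= 0 & ys <= 1))
  expect_lt(abs(rate_transfer(1e-12) - rate_transfer(-1e-12)), 1e-10)
  expect_equal(rate_transfer(-100), 0)
  expect_equal(rate_transfer(100), 1)
})

test_that("quiescent network sits at the baseline rate", {
  res <- build_reservoir(reservoir_params(N = 10, sigma_noise = 0,
                                          sigma_ini = 0, g = 0),
                         num_inputs = 2, seed = 1)
  sch <- trial_schedule(matrix(0, 2, 50), decision_time = 50)
  tr <- integrate_trial(res, sch, seed = 1, record_trace = TRUE)
  expect_true(all(abs(tr$rates - 0.1) < 1e-14))
})

test_that("Euler integration matches the analytic leak", {
  # single neuron, no recurrence/noise; drive the activation to a known
  # value through a constant input, then release and watch the decay
  params <- reservoir_params(N = 1, p = 1, g = 0, tau = 100, dt = 1,
                             sigma_noise = 0, sigma_ini = 0, g_IR = 1,
                             p_IR = 1)
  res <- build_reservoir(params, num_inputs = 1, seed = 1)
  res$W_in[1, 1] <- 1
  w <- 1  # x converges toward the input drive
  inputs <- matrix(0, 1, 300)
  inputs[1, 1:100] <- 1
  sch <- trial_schedule(inputs, decision_time = 300)
  tr <- integrate_trial(res, sch, seed = 1, record_trace = TRUE)
  a <- 1 / 100
  # closed-form Euler trajectory during the driven phase ...
  x_drive <- 1 - (1 - a)^(1:100)
  # ... and exponential-like decay after release
  x0 <- x_drive[100]
  x_decay <- x0 * (1 - a)^(1:200)
  x_ref <- c(x_drive, x_decay)
  y_ref <- ref_transfer(x_ref)
  expect_equal(as.numeric(tr$rates[, 1]), y_ref, tolerance = 1e-9)
  # Euler vs continuous-time decay: (1 - dt/tau)^100 ~ e^{-1} within 0.5%
  euler <- (1 - a)^100
  expect_equal(euler, 0.366032, tolerance = 1e-6)
  expect_lt(abs(euler - exp(-1)) / exp(-1), 0.0052)
})

test_that("trial integration is bit-reproducible and trial-indexed", {
  res <- tiny_reservoir()
  sch <- boxcar_schedule(3, rows = c(1, 3))
  a <- integrate_trial(res, sch, seed = 5, trial = 2)
  b <- integrate_trial(res, sch, seed = 5, trial = 2)
  expect_identical(a$rates_decision, b$rates_decision)
  c <- integrate_trial(res, sch, seed = 5, trial = 3)
  expect_false(identical(a$rates_decision, c$rates_decision))
})

test_that("schedule/reservoir mismatches raise shape errors", {
  res <- tiny_reservoir(num_inputs = 3)
  expect_error(integrate_trial(res, boxcar_schedule(2, 1), seed = 1),
               "input")
  sch <- boxcar_schedule(3, 1, duration = 50, on = 10, off = 40,
                         decision_time = 50)
  sch$decision_time <- 80
  expect_error(integrate_trial(res, sch, seed = 1), "decision")
})

test_that("rates stay within bounds across random drive", {
  res <- tiny_reservoir(N = 60, g = 2.5, sigma_noise = 0.05, sigma_ini = 0.2)
  for (k in 1:5) {
    sch <- boxcar_schedule(3, rows = c(1L + (k %% 3L), 1L), duration = 150)
    tr <- integrate_trial(res, sch, seed = k, record_trace = TRUE)
    expect_true(all(tr$rates >= 0 & tr$rates <= 1))
  }
})

test_that("empirical connection densities are consistent with p and p_IR", {
  # chi-square goodness of fit over 20 seeds, alpha = 0.01
  N <- 60; p <- 0.1; p_IR <- 0.2; M <- 3
  counts_rec <- counts_in <- numeric(20)
  for (s in 1:20) {
    res <- build_reservoir(reservoir_params(N = N, p = p, p_IR = p_IR), M, s)
    counts_rec[s] <- length(res$csr$values)
    counts_in[s] <- sum(res$W_in != 0)
  }
  chisq_rec <- sum((counts_rec - N^2 * p)^2 / (N^2 * p * (1 - p)))
  chisq_in <- sum((counts_in - N * M * p_IR)^2 / (N * M * p_IR * (1 - p_IR)))
  expect_lt(chisq_rec, qchisq(0.99, df = 20))
  expect_lt(chisq_in, qchisq(0.99, df = 20))
})
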