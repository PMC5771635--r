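test_that("reversal contingency rewards the correct side and flips per block", {
  cfg <- reversal_config()
  expect_equal(reversal_step(1, "A", cfg), 1L)
  expect_equal(reversal_step(1, "B", cfg), 0L)
  expect_equal(reversal_step(100, "A", cfg), 1L)
  # trial 101 starts block 2: contingency reversed
  expect_equal(reversal_step(101, "A", cfg), 0L)
  expect_equal(reversal_step(101, "B", cfg), 1L)
  expect_equal(reversal_step(201, "A", cfg), 1L)
})

test_that("reversal schedule activates the chosen and reward units in-window", {
  cfg <- reversal_config()
  sch <- make_reversal_schedule("A", 1, cfg)
  expect_equal(dim(sch$inputs), c(3, 900))
  win <- 201:700
  expect_true(all(sch$inputs["A", win] == 1))
  expect_true(all(sch$inputs["R", win] == 1))
  expect_true(all(sch$inputs["B", ] == 0))
  expect_true(all(sch$inputs[, -win] == 0))
  expect_equal(sch$decision_time, 900)
  # unrewarded: reward row silent
  sch0 <- make_reversal_schedule("B", 0, cfg)
  expect_true(all(sch0$inputs["R", ] == 0))
  expect_true(all(sch0$inputs["B", win] == 1))
  # lesion: only the choice row is ever active
  cfg_les <- reversal_config(reward_input = FALSE)
  schl <- make_reversal_schedule("B", 1, cfg_les)
  expect_true(all(schl$inputs["R", ] == 0))
  expect_true(all(schl$inputs["B", win] == 1))
  expect_equal(schl$decision_time, 900)
})

test_that("two-stage transitions occur at the common probability", {
  cfg <- twostage_config()
  n <- 10000
  us <- matrix(stream_uniforms(3, 4, 0, 2 * n), ncol = 2)
  interm <- vapply(seq_len(n), function(i)
    twostage_step(1, "A1", cfg, us[i, ])$intermediate, character(1))
  f <- mean(interm == "B1")
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(f - 0.8), 3 * se)
  # degenerate transition
  cfg1 <- twostage_config(common_prob = 1)
  expect_equal(twostage_step(1, "A2", cfg1, c(0.99, 0.5))$intermediate, "B2")
})

test_that("two-stage reward contingency reverses every 50 trials", {
  cfg <- twostage_config()
  # force the B1 intermediate and a reward draw below reward_prob_lo
  r_block1 <- twostage_step(1, "A1", cfg, c(0, 0.5))
  r_block2 <- twostage_step(51, "A1", cfg, c(0, 0.5))
  expect_equal(r_block1$intermediate, "B1")
  expect_equal(r_block1$reward, 1L)  # B1 good in block 1: p = 0.8 > 0.5
  expect_equal(r_block2$reward, 0L)  # B1 bad in block 2: p = 0.2 < 0.5
})

test_that("two-stage schedule sequences the events into their windows", {
  cfg <- twostage_config()
  sch <- make_twostage_schedule("A1", "B1", 1, cfg)
  expect_equal(dim(sch$inputs), c(6, 1900))
  expect_true(all(sch$inputs["A1", 201:700] == 1))
  expect_true(all(sch$inputs["B1", 701:1200] == 1))
  expect_true(all(sch$inputs["R", 1201:1700] == 1))
  expect_true(all(sch$inputs["N", ] == 0))
  expect_true(all(sch$inputs["A2", ] == 0))
  expect_true(all(sch$inputs[, 1:200] == 0))
  # non-reward trials activate N instead of R
  sch0 <- make_twostage_schedule("A2", "B2", 0, cfg)
  expect_true(all(sch0$inputs["N", 1201:1700] == 1))
  expect_true(all(sch0$inputs["R", ] == 0))
  # lesion variants: R only, or R and N
  cfg_r <- twostage_config(reward_input = FALSE)
  expect_true(all(make_twostage_schedule("A1", "B1", 1, cfg_r)$inputs["R", ] == 0))
  expect_true(all(make_twostage_schedule("A1", "B1", 0, cfg_r)$inputs["N", 1201:1700] == 1))
  cfg_rn <- twostage_config(reward_input = FALSE, nonreward_input = FALSE)
  expect_true(all(make_twostage_schedule("A1", "B1", 0, cfg_rn)$inputs[c("R", "N"), ] == 0))
  # B-first variant swaps the A and B windows
  cfg_bf <- twostage_config(event_order = "B-first")
  schb <- make_twostage_schedule("A1", "B1", 1, cfg_bf)
  expect_true(all(schb$inputs["B1", 201:700] == 1))
  expect_true(all(schb$inputs["A1", 701:1200] == 1))
})

test_that("offer input kernel matches its closed form", {
  cfg <- econ_config()
  g <- function(t) 1 / ((1 + exp(-(t - 475) / 30)) * (1 + exp((t - 700) / 100)))
  expect_equal(g(475), 0.452325, tolerance = 1e-6)
  expect_equal(g(700), 0.499724, tolerance = 1e-6)
  # profile is the range-adapted, peak-normalized kernel inside the window
  t <- c(200, 500, 700, 1200, 1350)
  f <- econ_input_profile(t, mag = 4, mag_max = 8, mag_min = 0, cfg)
  peak <- max(g(301:1300))
  expect_equal(f[2], 4 * g(500) / (8 * peak), tolerance = 1e-12)
  expect_equal(f[c(1, 5)], c(0, 0))  # silent outside the window
  # minimal offer is silent everywhere
  expect_true(all(econ_input_profile(301:1300, 0, 8, 0, cfg) == 0))
  expect_error(econ_input_profile(500, 1, 2, 2, cfg), "degenerate")
})

test_that("offer schedules are bounded and peak at the block maximum", {
  cfg <- econ_config()
  sch <- make_econ_schedule(3, 8, cfg)
  expect_true(all(sch$inputs >= 0 & sch$inputs <= 1))
  expect_equal(max(sch$inputs["offerA", ]), 1, tolerance = 1e-12)
  expect_equal(max(sch$inputs["offerB", ]), 1, tolerance = 1e-12)
  half <- make_econ_schedule(2, 4, cfg)
  expect_equal(max(half$inputs["offerB", ]), 0.5, tolerance = 1e-12)
  # step-function variant is flat over the window
  cfg_step <- econ_config(profile = "step")
  schs <- make_econ_schedule(3, 8, cfg_step)
  expect_true(all(schs$inputs["offerA", 301:1300] == 1))
  expect_true(all(schs$inputs["offerA", c(1:300, 1301:1400)] == 0))
})

test_that("economic expected value is the probability-weighted offer value", {
  expect_equal(econ_expected_value(c(0.5, 0.5), c(1, 2), gamma = 2), 2)
  expect_equal(econ_expected_value(c(0.3, 0.7), c(0, 0), gamma = 2), 0)
  expect_equal(econ_expected_value(c(1, 0), c(3, 5), gamma = 2), 6)
})

test_that("offer draws cover the grid but never the (0,0) pair", {
  cfg <- econ_config()
  draws <- t(vapply(1:2000, function(i)
    econ_draw_offers(cfg, stream_uniforms(11, 5, i, 2)), numeric(2)))
  expect_true(all(draws[, 1] %in% 0:3))
  expect_true(all(draws[, 2] %in% 0:8))
  expect_false(any(draws[, 1] == 0 & draws[, 2] == 0))
  expect_gt(length(unique(paste(draws[, 1], draws[, 2]))), 30)
})

test_that("event-task schedules are binary", {
  expect_true(all(make_reversal_schedule("A", 1, reversal_config())$inputs %in% c(0, 1)))
  expect_true(all(make_twostage_schedule("A1", "B2", 1, twostage_config())$inputs %in% c(0, 1)))
})
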