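test_that("resting-window selection ties break to the earliest start", {
  w <- select_resting_window(rep(1, 2400), n_low = 1200, n_stable = 600)
  expect_equal(w$start, 1)
  expect_equal(w$end, 601)
  expect_equal(w$co2_sd, 0)
})

test_that("a planted low-and-flat segment is selected exactly", {
  set.seed(42)
  x <- 5 + rnorm(4800, 0, 0.5)           # noisy high baseline
  x[2001:2600] <- 1 + rnorm(600, 0, 1e-4)  # low, flat 5-min segment
  w <- select_resting_window(x, 1200, 600)
  expect_equal(w$start, 2001)              # exactly the planted segment
  expect_identical(w$start, brute_force_window(x, 1200, 600))
})

test_that("V-shaped series selection agrees with exhaustive search", {
  x <- abs(seq(-2400, 2399)) / 1000 + 3
  w <- select_resting_window(x, 1200, 600)
  expect_equal(w$start, brute_force_window(x, 1200, 600))
  # the 10-min window is centred on the minimum of the V
  expect_equal(w$low_start, 2401 - 600)
})

test_that("selection equals exhaustive search on random series", {
  for (s in 1:60) {
    set.seed(s)
    n <- sample(1200:4800, 1)
    x <- cumsum(rnorm(n)) + rnorm(n, 0, 0.2)
    expect_identical(select_resting_window(x, 1200, 600)$start,
                     brute_force_window(x, 1200, 600))
  }
  # short stretches are skipped with a message
  expect_message(w <- select_resting_window(rnorm(1000), 1200, 600),
                 "skipped")
  expect_null(w)
})

test_that("stretch tiling follows the step arithmetic", {
  sim <- generate_respirometry_trial(physiology_params(),
                                     cbind(c(25, 30), c(120, 39)), seed = 5,
                                     activity = FALSE)
  steps <- sim$truth$steps
  expect_message(cand <- segment_trial(sim$trace, steps),
                 "no complete")
  expect_equal(sum(cand$step == 1), 3)   # 120 min -> 3 stretches
  expect_equal(sum(cand$step == 2), 0)   # 39 min -> none
})

test_that("activity threshold follows the min (or mean) rule with fallback", {
  sim <- generate_respirometry_trial(physiology_params(), cbind(25, 60),
                                     seed = 6, activity = FALSE)
  iv <- data.frame(start_s = c(300, 1500), end_s = c(600, 1800))
  tr <- sim$trace
  sd1 <- sd(tr$fe_co2[tr$time >= 300 & tr$time < 600])
  sd2 <- sd(tr$fe_co2[tr$time >= 1500 & tr$time < 1800])
  expect_equal(activity_threshold(tr, iv, rule = "min"), min(sd1, sd2))
  expect_equal(activity_threshold(tr, iv, rule = "mean"), mean(c(sd1, sd2)))
  expect_message(tau <- activity_threshold(tr, NULL), "quantile")
  expect_gt(tau, 0)
})

test_that("exclusion tests flag settle-in, disruptions and activity", {
  cand <- data.frame(step = c(1, 1, 2, 2), ta_set = c(25, 25, 30, 30),
                     stretch = 1:4,
                     start_s = c(1500, 4000, 10900, 12000),
                     end_s = c(1800, 4300, 11200, 12300),
                     i_start = 1L, i_end = 2L,
                     co2_mean = c(1, 2, 3, 2.5), co2_sd = c(1, 1, 1, 9))
  ev <- data.frame(time = 7200, kind = "disruption", note = "")
  out <- apply_exclusion_tests(cand, ev, tau = 5)
  expect_true(out$settle_in[1])            # overlaps first hour
  expect_false(out$retained[1])
  expect_true(out$disruption[2])           # 4000-4300 within 7200 +/- 3600
  expect_false(out$disruption[3])          # 10900 outside the radius
  expect_true(out$activity[4])             # co2_sd 9 >= tau 5
  expect_true(out$retained[3])
  expect_equal(sum(out$best), 1)
  expect_true(out$best[3])
})

test_that("one best estimate per non-empty step; disruptions only remove", {
  sim <- generate_respirometry_trial(physiology_params(), test_schedule(),
                                     seed = 9)
  bouts <- extract_rmr(sim$trace, sim$truth$steps,
                       active_intervals = sim$truth$activity)
  per_step <- tapply(bouts$best, bouts$step, sum)
  ret_step <- tapply(bouts$retained, bouts$step, any)
  expect_true(all(per_step[ret_step] == 1))
  expect_true(all(per_step[!ret_step] == 0))

  # monotone safety: adding a disruption never increases retained bouts
  cand <- segment_trial(sim$trace, sim$truth$steps)
  base <- apply_exclusion_tests(cand, NULL, tau = Inf)
  n0 <- sum(base$retained)
  for (d in seq(0, 18000, by = 3000)) {
    ev <- data.frame(time = d, kind = "disruption", note = "")
    expect_lte(sum(apply_exclusion_tests(cand, ev, tau = Inf)$retained), n0)
  }
})

test_that("retained candidates lie inside true quiet spans", {
  sim <- generate_respirometry_trial(physiology_params(), test_schedule(),
                                     seed = 13)
  bouts <- extract_rmr(sim$trace, sim$truth$steps,
                       active_intervals = sim$truth$activity)
  act <- sim$truth$activity
  ret <- bouts[bouts$retained, ]
  for (i in seq_len(nrow(ret)))
    expect_false(any(act$start_s < ret$end_s[i] &
                       ret$start_s[i] < act$end_s))
})
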