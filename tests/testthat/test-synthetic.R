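test_that("trial generator enforces its contracts", {
  p <- physiology_params()
  expect_error(generate_respirometry_trial(p, cbind(c(30, 25), c(60, 60)),
                                           seed = 1), "non-decreasing")
  expect_error(generate_respirometry_trial(p, cbind(25, 60), seed = 1,
                                           washout_tau = -1), "washout_tau")
  expect_error(physiology_params(rq = 1.3), "rq")
  expect_error(physiology_params(slope_below_lct = 2), "negative")
})

test_that("forward model is flat inside the thermoneutral zone", {
  p <- physiology_params()  # lct 29.8
  sim <- generate_respirometry_trial(p, cbind(35, 2), seed = 1,
                                     noise_sd = 0, activity = FALSE,
                                     washout_tau = 0)
  expect_equal(unique(sim$truth$rates$vo2), p$bmr)
  expect_equal(sim$truth$steps$vo2_true, p$bmr)
})

test_that("trace obeys exact per-sample mass balance", {
  sim <- generate_respirometry_trial(physiology_params(), cbind(c(24, 30),
                                                                c(30, 30)),
                                     seed = 2, noise_sd = 0)
  tr <- sim$trace
  # infer outflow from nitrogen balance and check each species' budget
  fe_n2 <- 1 - tr$fe_o2 - tr$fe_co2 - tr$fe_h2o
  fi_n2 <- 1 - tr$fi_o2 - tr$fi_co2 - tr$fi_h2o
  outflow <- tr$flow * fi_n2 / fe_n2
  vo2 <- (tr$flow * tr$fi_o2 - outflow * tr$fe_o2) * 60
  vco2 <- (outflow * tr$fe_co2 - tr$flow * tr$fi_co2) * 60
  # analyzer-side rates are the washout-filtered truth; reconstruct them
  r <- rates_from_fractions(tr)
  expect_equal(r$vo2, vo2, tolerance = 1e-12)
  expect_equal(r$vco2, vco2, tolerance = 1e-12)
  # and inflow - outflow equals net gas exchange at every sample
  expect_equal(tr$flow - outflow, (vo2 - vco2) / 60 - r$vh2o / 60 / 0.803,
               tolerance = 1e-9)
})

test_that("generator output is deterministic in (params, seed)", {
  a <- generate_respirometry_trial(physiology_params(), test_schedule(),
                                   seed = 11)
  b <- generate_respirometry_trial(physiology_params(), test_schedule(),
                                   seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth, b$truth)
  f1 <- generate_free_ranging(rhythm_params(), site(), 3, seed = 5)
  f2 <- generate_free_ranging(rhythm_params(), site(), 3, seed = 5)
  expect_identical(f1$tb, f2$tb)
  expect_identical(f1$ta, f2$ta)
})

test_that("ground truth plants usable resting windows in every step", {
  sim <- generate_respirometry_trial(physiology_params(), test_schedule(),
                                     seed = 1)
  rw <- sim$truth$resting_windows
  expect_true(all(sim$truth$steps$step %in% rw$step))
  # planted windows lie after settle-in and outside activity intervals
  expect_true(all(rw$start_s >= 3600))
  act <- sim$truth$activity
  for (i in seq_len(nrow(rw)))
    expect_false(any(act$start_s < rw$end_s[i] & rw$start_s[i] < act$end_s))
})

test_that("breakpoint dataset generator honours its contract and model", {
  expect_error(generate_breakpoint_dataset(50, c(-1, 0), 1, c(20, 40), 20,
                                           0, 1), "psi")
  expect_error(generate_breakpoint_dataset(30, c(-1, 0), 1, c(20, 40), 5,
                                           0, 1), "n must be")
  d <- generate_breakpoint_dataset(30, c(-0.5, 0.2), 16, c(20, 40), 100,
                                   0, seed = 3)
  # zero noise: data lie exactly on the two-segment surface
  expect_equal(d$y, 16 - 0.5 * d$x + 0.7 * pmax(0, d$x - 30),
               tolerance = 1e-12)
  f <- fit_piecewise(d$x, d$y)
  expect_equal(f$psi, 30, tolerance = 1e-6)
})

test_that("field generator phase geometry holds at zero noise", {
  rp <- rhythm_params(noise_sd = 0, torpor_prob_per_day = 0)
  f <- generate_free_ranging(rp, site(), 3, seed = 2)
  ev <- f$truth$events
  tn <- as.numeric(f$tb$timestamp)
  # distance to the nearest solar event, in seconds
  evt <- sort(as.numeric(c(ev$sunrise, ev$sunset)))
  nearest <- vapply(tn, function(t) min(abs(t - evt)), numeric(1))
  ph <- solar_phase(f$tb$timestamp, site())$phase
  outside <- nearest > rp$transition_minutes * 60 / 2
  expect_gt(min(f$tb$temperature[ph == "night" & outside]),
            max(f$tb$temperature[ph == "day" & outside]))
  expect_error(generate_free_ranging(rp, site(), 1, seed = 1), "n_days")
})

test_that("paired-temperature generator recovers the planted offset", {
  pairs <- generate_paired_temps(400, offset = -0.72, sd = 0.25, seed = 8)
  off <- subq_core_offset(pairs)
  expect_equal(off$mean, -0.72, tolerance = 0.05)
  expect_equal(off$sd, 0.25, tolerance = 0.05)
})
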