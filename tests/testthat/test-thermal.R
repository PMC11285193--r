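test_that("ambient matching is nearest-in-time with a gap cutoff", {
  tz <- "America/New_York"
  tb <- data.frame(timestamp = as.POSIXct("2018-07-01 12:00", tz = tz),
                   temperature = 37.5)
  ta <- data.frame(timestamp = as.POSIXct(c("2018-07-01 11:45",
                                            "2018-07-01 12:30"), tz = tz),
                   temperature = c(24, 26))
  expect_equal(match_ambient(tb, ta)$t_a, 24)       # 15 min beats 30 min
  ta2 <- data.frame(timestamp = as.POSIXct("2018-07-01 13:10", tz = tz),
                    temperature = 30)
  expect_true(is.na(match_ambient(tb, ta2)$t_a))    # 70 min > 45 min
  expect_warning(m <- match_ambient(tb, ta2[0, ]), "empty")
  expect_true(is.na(m$t_a))

  # aligned 5-min / 45-min grids never exceed a 22.5-min matching gap
  f <- generate_free_ranging(rhythm_params(), site(), 3, seed = 3)
  m <- match_ambient(f$tb, f$ta)
  inside <- m$timestamp >= min(f$ta$timestamp) &
    m$timestamp <= max(f$ta$timestamp)   # grid arithmetic holds interior
  k <- vapply(as.numeric(m$timestamp[inside]), function(t)
    min(abs(t - as.numeric(f$ta$timestamp))), numeric(1))
  expect_lte(max(k), 22.5 * 60)
})

test_that("phase summaries compute the documented statistics", {
  prof <- data.frame(individual = "a",
                     timestamp = as.POSIXct("2018-07-01", tz = "UTC") +
                       (1:3) * 300,
                     t_b = c(37.0, 37.0, 38.5), t_a = NA_real_,
                     phase = factor("day", levels = c("day", "night")),
                     squirrel_date = as.Date("2018-07-01"))
  ps <- phase_summaries(prof)
  expect_equal(ps$phases$mode_tb, 37.0)
  expect_equal(ps$phases$mean_tb, 37.5)
  expect_equal(ps$phases$range_tb, 1.5)
  expect_equal(ps$phases$sd_tb, sd(c(37, 37, 38.5)))

  prof$t_b <- 37.2
  ps2 <- phase_summaries(prof)
  expect_equal(ps2$phases$mode_tb, ps2$phases$mean_tb)
  expect_equal(ps2$phases$sd_tb, 0)
  expect_equal(ps2$phases$range_tb, 0)
})

test_that("binned mode is order-invariant and duplicate-stable", {
  x <- c(37.1, 37.1, 37.2, 39.9, 39.9, 39.9)
  expect_equal(mode_binned(x), 39.9)
  expect_equal(mode_binned(rev(x)), 39.9)
  expect_equal(mode_binned(sample(c(x, 39.9, 39.9))), 39.9)
  expect_equal(mode_binned(c(37.1, 39.9)), 37.1)   # tie -> lower centre
})

test_that("Heterothermy Index matches its closed form", {
  expect_equal(heterothermy_index(rep(39.9, 50), 39.9), 0)
  expect_equal(heterothermy_index(c(37, 38, 39), 39), sqrt(5 / 2))
  expect_equal(round(heterothermy_index(c(37, 38, 39), 39), 4), 1.5811)
  expect_error(heterothermy_index(37, 39), "2 records")
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(sample(10:200, 1), 38, 1)
    m <- rnorm(1, 39, 0.5)
    expect_equal(heterothermy_index(x, m), hi_oracle(x, m))
  }
})

test_that("torpor detection applies the threshold-and-duration rule", {
  tz <- "UTC"
  t0 <- as.POSIXct("2018-07-01", tz = tz)
  mk <- function(temps) data.frame(timestamp = t0 +
                                     seq_along(temps) * 300,
                                   temperature = temps)
  expect_equal(nrow(detect_torpor(mk(rep(37, 50)))), 0)

  bout <- detect_torpor(mk(c(rep(37, 5), rep(34.6, 12), rep(37, 5))))
  expect_equal(nrow(bout), 1)
  expect_equal(bout$min_tb, 34.6)
  expect_equal(as.numeric(bout$end - bout$start, units = "mins"), 55)
  expect_equal(bout$n_records, 12)                  # 60 min of samples

  # two 20-min dips separated by one warm sample: no 30-min bout
  dips <- c(rep(37, 4), rep(34.8, 4), 37, rep(34.8, 4), rep(37, 4))
  expect_equal(nrow(detect_torpor(mk(dips))), 0)
})

test_that("cosinor recovers a pure cosine exactly and degrades gracefully", {
  t0 <- as.POSIXct("2018-06-01", tz = "UTC")
  td <- seq(0, 3, by = 1 / 288)
  tb <- data.frame(timestamp = t0 + td * 86400,
                   temperature = 38.7 + 1.2 * cos(2 * pi * td))
  r <- daily_rhythm(tb)
  expect_equal(r$period, 1.00)
  expect_equal(r$amplitude, 2.4, tolerance = 1e-6)
  expect_equal(r$mesor, 38.7, tolerance = 1e-6)

  const <- data.frame(timestamp = t0 + td * 86400, temperature = 38)
  rc <- daily_rhythm(const)
  expect_equal(rc$amplitude, 0)
  expect_false(rc$period_defined)
})

test_that("deployment filtering drops the first week and lab visits", {
  tz <- "UTC"
  t0 <- as.POSIXct("2018-06-01", tz = tz)
  tb <- data.frame(timestamp = t0 + seq(0, 10 * 86400 - 300, by = 300),
                   temperature = 38)
  out <- preprocess_deployment(tb)
  expect_equal(nrow(out), 3 * 288)
  visit <- data.frame(start = t0 + 8 * 86400, end = t0 + 9 * 86400)
  out2 <- preprocess_deployment(tb, visit)
  expect_equal(nrow(out2), 2 * 288)
  short <- tb[tb$timestamp < t0 + 6 * 86400, ]
  expect_warning(out3 <- preprocess_deployment(short), "no records")
  expect_equal(nrow(out3), 0)
})

test_that("subcutaneous-core offset statistics", {
  p <- data.frame(t_sub = c(36.8, 37.0), t_core = c(37.5, 37.7))
  off <- subq_core_offset(p)
  expect_equal(off$mean, -0.7)
  expect_equal(off$sd, 0)
  same <- data.frame(t_sub = c(37, 38), t_core = c(37, 38))
  expect_equal(subq_core_offset(same)$mean, 0)
  expect_error(subq_core_offset(p[1, ]), "pairs")
})

test_that("field defaults land in the observed heterothermy range", {
  f <- generate_free_ranging(rhythm_params(), site(), 30, seed = 7)
  p <- thermal_profile(f$tb, f$ta, site())
  # pooled phase modes within one bin of the generating plateaus
  expect_lte(abs(mode_binned(p$t_b[p$phase == "day"]) - 37.5), 0.1 + 1e-9)
  expect_lte(abs(mode_binned(p$t_b[p$phase == "night"]) - 39.9), 0.1 + 1e-9)
  hi <- daily_hi(p)
  expect_gt(mean(hi$hi), 1.5)
  expect_lt(mean(hi$hi), 2.5)
  rr <- daily_rhythm_by_date(p)
  expect_gt(mean(rr$amplitude), 3.0)
  expect_lt(mean(rr$amplitude), 4.4)
  expect_equal(median(rr$period), 1, tolerance = 0.1)
})
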