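test_that("empty chamber yields zero rates", {
  tr <- data.frame(fe_o2 = 0.2095, fe_co2 = 4e-4, fe_h2o = 0.005,
                   fi_o2 = 0.2095, fi_co2 = 4e-4, fi_h2o = 0.005,
                   flow = 1000)
  r <- rates_from_fractions(tr)
  expect_equal(r$vo2, 0)
  expect_equal(r$vco2, 0)
  expect_equal(r$vh2o, 0)
  expect_false(r$flagged)
})

test_that("nitrogen-balance equations invert a hand-built mass balance", {
  # true rates: VO2 1.0, VCO2 0.85 ml/min; VH2O 2 mg/min = 2/0.803 ml/min
  fr <- fractions_from_rates(1000, 0.2095, 4e-4, 0.005,
                             1.0, 0.85, 2 / 0.803)
  r <- rates_from_fractions(fr)
  expect_equal(r$vo2, 60, tolerance = 1e-9)
  expect_equal(r$vco2, 0.85 * 60, tolerance = 1e-9)
  expect_equal(r$vh2o, 120, tolerance = 1e-9)
})

test_that("rates are invariant to flow given scaled fraction differentials", {
  r1 <- rates_from_fractions(
    fractions_from_rates(500, 0.2095, 4e-4, 0.005, 1.2, 1.0, 2.5))
  r2 <- rates_from_fractions(
    fractions_from_rates(2000, 0.2095, 4e-4, 0.005, 1.2, 1.0, 2.5))
  expect_equal(r1$vo2, r2$vo2, tolerance = 1e-12)
  expect_equal(r1$vco2, r2$vco2, tolerance = 1e-12)
  expect_equal(r1$vh2o, r2$vh2o, tolerance = 1e-12)
})

test_that("nitrogen fraction guard trips on impossible fractions", {
  tr <- data.frame(fe_o2 = 0.5, fe_co2 = 0.3, fe_h2o = 0.21,
                   fi_o2 = 0.2095, fi_co2 = 4e-4, fi_h2o = 0.005,
                   flow = 1000)
  expect_error(rates_from_fractions(tr), "nitrogen")
})

test_that("energetics computes the oxyjoule and latent-heat conversions", {
  e <- energetics(data.frame(vo2 = 1000, vco2 = 1000, vh2o = 0))
  expect_equal(e$rq, 1)
  expect_equal(e$mhp, 21164)
  expect_equal(e$ehl, 0)
  expect_equal(e$ehl_mhp, 0)

  e2 <- energetics(data.frame(vo2 = 1000, vco2 = 850, vh2o = 500))
  expect_equal(e2$ehl_mhp, (2.41 * 500) / (1000 * (16 + 5.164 * 0.85)),
               tolerance = 1e-12)
  expect_equal(round(e2$ehl_mhp, 3), 0.059)

  expect_warning(e3 <- energetics(data.frame(vo2 = 100, vco2 = 130,
                                             vh2o = 1)), "RQ")
  expect_true(e3$rq_suspect)
  expect_error(energetics(data.frame(vo2 = 0, vco2 = 1, vh2o = 1)), "vo2")
})

test_that("mass-specific scaling divides extensive rates and round-trips", {
  r <- data.frame(vo2 = 60, vco2 = 51, vh2o = 120, rq = 0.85)
  ms <- mass_specific(r, 60)
  expect_equal(ms$vo2, 1)
  expect_equal(ms$rq, 0.85)  # intensive, unchanged
  back <- ms
  for (k in c("vo2", "vco2", "vh2o")) back[[k]] <- back[[k]] * 60
  expect_equal(back$vo2, r$vo2)
  expect_error(mass_specific(r, 0), "mass_g")
})

test_that("analyzer inversion reproduces the generator forward model", {
  # spot-check of the closed generator/analyzer loop (bulk version in the
  # acceptance suite)
  for (s in 1:25) {
    set.seed(s)
    p <- physiology_params(bmr = runif(1, 50, 150),
                           lct = runif(1, 27, 32),
                           slope_below_lct = -runif(1, 4, 14),
                           ewl_base = runif(1, 30, 90),
                           rq = runif(1, 0.7, 1.0))
    ta <- runif(1, 20, 40)
    sim <- generate_respirometry_trial(p, cbind(ta, 1), seed = s,
                                       noise_sd = 0, activity = FALSE,
                                       washout_tau = 0)
    r <- rates_from_fractions(sim$trace)
    expect_equal(r$vo2, sim$truth$rates$vo2, tolerance = 1e-9)
    expect_equal(r$vco2, sim$truth$rates$vco2, tolerance = 1e-9)
    expect_equal(r$vh2o, sim$truth$rates$vh2o, tolerance = 1e-9)
  }
})
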