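test_that("AICc arithmetic, limits and contracts", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(0, 2, 10), 5.7142857, tolerance = 1e-7)
  expect_equal(aicc(-5, 0, 10), 10)                       # k = 0
  # large-n limit equals plain AIC
  expect_lt(abs(aicc(-100, 3, 1e8) - (2 * 100 + 2 * 3)), 1e-6)
  expect_error(aicc(0, 5, 6), "n <= k")
})

test_that("Akaike weights: symmetry, known pair, shift invariance", {
  expect_equal(akaike_weights(c(10, 10)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(0.7310586, 0.2689414), tolerance = 1e-6)
  expect_equal(sum(w), 1)
  a <- c(103.2, 101.7, 110.4)
  expect_equal(akaike_weights(a), akaike_weights(a + 57.3))
  expect_equal(akaike_weights(c(1e8, 1e8 + 2))[1], 0.7310586,
               tolerance = 1e-6)  # overflow-safe
  expect_error(akaike_weights(c(Inf, Inf)), "finite")
})

test_that("driver comparison validates predictors and ranks sensibly", {
  set.seed(31)
  d <- data.frame(day_of_year = rep(150:179, 3),
                  ta_max = rnorm(90, 24, 3),
                  individual = rep(c("a", "b", "c"), each = 30))
  d$max_tb <- 40 + 0.08 * (d$ta_max - 24) + rnorm(90, 0, 0.15)
  cmp <- compare_tb_models(d, "max_tb")
  expect_s3_class(cmp, "model_comparison")
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-9)
  expect_equal(cmp$delta_aicc[1], 0)
  expect_true(grepl("ta_max", cmp$model[1]))
  expect_error(compare_tb_models(d, "max_tb",
                                 candidates = list("no_such")), "unknown")
  expect_error(compare_tb_models(d, "absent"), "response")
  expect_output(print(cmp), "squirrel-days")
})

test_that("duplicating rows keeps coefficients, shifts AICc with n", {
  set.seed(32)
  d <- data.frame(day_of_year = 150:189, ta_max = rnorm(40, 24, 3),
                  individual = "solo")
  d$max_tb <- 40 - 0.002 * d$day_of_year + rnorm(40, 0, 0.2)
  c1 <- compare_tb_models(d, "max_tb", candidates = list("day_of_year"))
  c2 <- compare_tb_models(rbind(d, d), "max_tb",
                          candidates = list("day_of_year"))
  f1 <- attr(c1, "fits")[[1]]; f2 <- attr(c2, "fits")[[1]]
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  # doubled data: loglik doubles exactly for the same OLS solution,
  # and the small-sample correction shrinks with n
  expect_equal(c2$loglik, 2 * c1$loglik, tolerance = 1e-6)
  expect_equal(c2$aicc,
               -2 * c2$loglik + 2 * c2$k +
                 2 * c2$k * (c2$k + 1) / (80 - c2$k - 1))
})

test_that("random intercept with no between-individual variance gives OLS", {
  set.seed(33)
  d <- data.frame(x = rnorm(120), individual = rep(letters[1:4], 30))
  d$y <- 2 + 0.5 * d$x + rnorm(120, 0, 0.3)   # no individual effect
  cmp <- compare_tb_models(d, "y", candidates = list("x"))
  fe <- lme4::fixef(attr(cmp, "fits")[[1]])
  ols <- coef(lm(y ~ x, d))
  expect_equal(unname(fe), unname(ols), tolerance = 1e-6)
})
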