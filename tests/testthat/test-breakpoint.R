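test_that("noiseless two-segment geometry is recovered exactly", {
  x <- seq(20, 40, length.out = 41)
  y <- 10 - 0.5 * x + 0.5 * pmax(0, x - 30)  # slopes (-0.5, 0) meeting at 30
  f <- fit_piecewise(x, y)
  expect_equal(f$psi, 30, tolerance = 1e-6)
  expect_equal(f$slope_left, -0.5, tolerance = 1e-9)
  expect_equal(f$slope_right, 0, tolerance = 1e-9)
  expect_equal(f$intercept, 10, tolerance = 1e-8)
  expect_true(f$converged)
})

test_that("contracts: n, span, starting value", {
  expect_error(fit_piecewise(1:6, rnorm(6)), "n >= 8")
  expect_error(fit_piecewise(seq(20, 22, length.out = 20), rnorm(20)),
               "span")
  d <- generate_breakpoint_dataset(30, c(-1, 0), 10, c(20, 40), 20, 0.1, 1)
  expect_error(fit_piecewise(d$x, d$y, psi0 = 50), "psi0")
})

test_that("iterative and grid routes agree to within the grid step", {
  for (s in 1:40) {
    d <- generate_breakpoint_dataset(28 + 3 * (s %% 3), c(-1, 0.2), 40,
                                     c(20, 40), 60, 1.0, seed = s)
    f_it <- fit_piecewise(d$x, d$y)
    gl <- min(d$x) + 0.05; gh <- max(d$x) - 0.05
    g <- squirreltherm:::grid_psi(d$x, d$y, NULL, gl, gh, 0.05)
    if (f_it$method == "iterative" && f_it$converged)
      expect_lte(abs(f_it$psi - g$psi), 0.05 + 1e-9)
  }
})

test_that("fit invariants: CI brackets psi, psi inside data range", {
  for (s in 1:30) {
    d <- generate_breakpoint_dataset(33, c(-0.8, 0.1), 30, c(22, 41),
                                     40, 1.5, seed = s + 100)
    f <- fit_piecewise(d$x, d$y)
    expect_lte(f$ci[1], f$psi)
    expect_gte(f$ci[2], f$psi)
    expect_gt(f$psi, min(d$x))
    expect_lt(f$psi, max(d$x))
  }
})

test_that("covariates: constant mass leaves the fit unchanged; order-free", {
  d <- generate_breakpoint_dataset(30, c(-2, 0), 80, c(20, 40), 53, 1, 7)
  f0 <- fit_piecewise(d$x, d$y)
  f1 <- fit_piecewise(d$x, d$y, covariates = data.frame(mass_g = 60.6))
  expect_equal(f1$psi, f0$psi, tolerance = 1e-8)
  expect_equal(unname(coef(f1)["mass_g"]), 0)

  perm <- sample(seq_along(d$x))
  f2 <- fit_piecewise(d$x[perm], d$y[perm])
  expect_equal(f2$psi, f0$psi, tolerance = 1e-8)
  expect_equal(f2$ci, f0$ci, tolerance = 1e-8)
})

test_that("a real mass covariate is estimated alongside the breakpoint", {
  set.seed(21)
  x <- runif(80, 20, 40)
  mass <- runif(80, 49, 79)
  y <- 100 - 4 * x + 4 * pmax(0, x - 29.8) + 1.2 * mass + rnorm(80, 0, 3)
  f <- fit_piecewise(x, y, covariates = data.frame(mass_g = mass))
  expect_equal(f$psi, 29.8, tolerance = 1)
  expect_equal(unname(coef(f)["mass_g"]), 1.2, tolerance = 0.3)
})

test_that("model methods behave like standard fitted-model accessors", {
  d <- generate_breakpoint_dataset(30, c(-1, 0), 40, c(20, 40), 40, 0.5, 2)
  f <- fit_piecewise(d$x, d$y)
  expect_length(residuals(f), 40)
  expect_equal(fitted(f) + residuals(f), d$y)
  expect_equal(predict(f), fitted(f))
  nd <- data.frame(x = c(25, 35))
  pr <- predict(f, nd)
  expect_equal(diff(pr), f$slope_left * 10 +
                 (f$slope_right - f$slope_left) * (35 - f$psi),
               tolerance = 1e-8)
  ll <- logLik(f)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 5)
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(40, 3))
  ci <- confint(f)
  expect_equal(unname(ci[1, ]), f$ci)
  expect_output(print(f), "breakpoint")
  expect_output(print(summary(f)), "Coefficients")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})

test_that("bootstrap CI brackets the estimate and stays in-range", {
  d <- generate_breakpoint_dataset(30, c(-2, 0), 80, c(20, 40), 53, 1.5, 3)
  f <- fit_piecewise(d$x, d$y, ci = "boot", n_boot = 99, boot_seed = 4)
  expect_equal(f$ci_method, "bootstrap-ci")
  expect_lte(f$ci[1], f$psi + 0.5)
  expect_gte(f$ci[2], f$psi - 0.5)
  expect_gte(f$ci[1], min(d$x))
  expect_lte(f$ci[2], max(d$x))
})

test_that("breakpoint-absence test separates linear from broken data", {
  x <- seq(20, 40, length.out = 30)
  r <- test_no_breakpoint(x, 5 - 0.2 * x)          # exact line
  expect_equal(r$verdict, "no-breakpoint")

  d <- generate_breakpoint_dataset(30, c(0, 0.5), 1.5, c(20, 40), 53,
                                   0.05, seed = 5)
  r2 <- test_no_breakpoint(d$x, d$y)
  expect_equal(r2$verdict, "breakpoint-supported")
  expect_gte(r2$delta_aicc, 2)
})

test_that("response suite fits the four thermal responses and skips thin ones", {
  study <- simulate_respirometry_study(n_trials = 8, seed = 17)
  suite <- suppressMessages(fit_response_suite(study$bouts))
  for (nm in c("vo2", "ewl", "tsub", "ehl_mhp"))
    expect_s3_class(suite[[nm]], "piecewise_fit")
  expect_true(!is.null(suite$vo2_upper$verdict))
  expect_output(print(suite), "critical temperature")

  few <- study$bouts[1:4, ]
  few$retained <- TRUE
  s2 <- fit_response_suite(few)
  expect_true(s2$vo2$skipped)
  expect_match(s2$vo2$reason, "retained bouts")
})
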