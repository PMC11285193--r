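#' Two-segment (breakpoint) linear regression
#'
#' Fits `y = b0 + b1*x + (b2 - b1)*(x - psi)+ [+ covariates]` with unknown
#' breakpoint `psi`, the model used to locate thermoneutral-zone limits
#' (lower critical temperature from VO2, and the inflections of evaporative
#' water loss, subcutaneous temperature and EHL/MHP against ambient
#' temperature).
#'
#' Estimation is by iterative linearization: at each step the working model
#' `y ~ x + (x - psi)+ + I(x > psi) + covariates` is fitted by least squares
#' and the breakpoint updated by `psi <- psi - gamma / beta2`, where `gamma`
#' is the coefficient of the indicator and `beta2` the slope-difference
#' coefficient (the first-order expansion of the hinge in psi). Convergence
#' is declared when the update falls below `tol`; if the iteration fails to
#' converge or the breakpoint escapes the data range, the fit falls back to a
#' profile grid search over candidate breakpoints.
#'
#' Confidence intervals: the breakpoint is a non-regular parameter, so no
#' single first-order interval is reliably calibrated across signal
#' strengths. The default `"hybrid"` interval is the smallest interval
#' containing both (i) the Wald (delta-method) interval,
#' `psi +/- t * SE(gamma)/|beta2|`, which captures local curvature but is
#' symmetric and can be too short when few points lie beyond the break, and
#' (ii) the likelihood-ratio (profile RSS) region at a 1-df calibration,
#' which captures asymmetry but can be too short when the RSS profile is
#' kinked at design points under strong signal. Pure `"delta"`,
#' `"profile"` and percentile `"boot"` intervals are available.
#'
#' @param x Numeric predictor (ambient temperature, degC); must span >= 5
#'   units, n >= 8.
#' @param y Numeric response.
#' @param covariates Optional data frame / matrix of additional linear
#'   covariates (e.g. body mass).
#' @param psi0 Starting breakpoint; default the median of `x`.
#' @param ci `"hybrid"` (default), `"delta"`, `"profile"` or `"boot"`.
#' @param n_boot Bootstrap replicates when `ci = "boot"`. Default 999.
#' @param boot_seed Seed for the bootstrap. Default 1.
#' @param grid_step Grid-search resolution, x units. Default 0.05.
#' @param tol Convergence tolerance on psi. Default 1e-4.
#' @param max_iter Maximum iterations. Default 50.
#' @param level Confidence level. Default 0.95.
#' @return An object of class `piecewise_fit` with components `psi`, `ci`,
#'   `slope_left`, `slope_right`, `intercept`, `coefficients`, `n`, `sigma`,
#'   `converged`, `iterations`, `method`, `fitted.values`, `residuals`.
#' @examples
#' d <- generate_breakpoint_dataset(30, c(-0.5, 0), 16, c(20, 40),
#'                                  n = 40, noise_sd = 0, seed = 1)
#' fit <- fit_piecewise(d$x, d$y)
#' fit$psi
#' coef(fit)
#' @seealso [test_no_breakpoint()], [fit_response_suite()]
#' @export
fit_piecewise <- function(x, y, covariates = NULL, psi0 = stats::median(x),
                          ci = c("hybrid", "delta", "profile", "boot"),
                          n_boot = 999,
                          boot_seed = 1, grid_step = 0.05,
                          tol = 1e-4, max_iter = 50, level = 0.95) {
  ci <- match.arg(ci)
  keep <- stats::complete.cases(x, y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) == 1)
      covariates <- covariates[rep(1, length(x)), , drop = FALSE]
    if (nrow(covariates) != length(x))
      stop("covariates must have one row per observation", call. = FALSE)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 8) stop("contract error: need n >= 8 observations", call. = FALSE)
  if (diff(range(x)) < 5)
    stop("contract error: x must span at least 5 units", call. = FALSE)
  if (psi0 <= min(x) || psi0 >= max(x))
    stop("psi0 must lie inside the range of x", call. = FALSE)

  cm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  lo <- min(x) + grid_step
  hi <- max(x) - grid_step

  rss_at <- function(p)
    sum(stats::lm.fit(cbind(1, x, pmax(0, x - p), cm), y)$residuals^2)

  # iterative solution, checked against the global RSS profile: the
  # linearization is local, so a solve that converged onto a secondary
  # optimum is re-polished from the grid minimiser
  it <- iterate_psi(x, y, cm, psi0, lo, hi, tol, max_iter)
  pr <- profile_rss(x, y, cm, lo, hi, grid_step)
  g_psi <- pr$grid[which.min(pr$rss)]
  rss_g <- min(pr$rss)
  method <- "iterative"
  if (!it$converged || rss_at(it$psi) > rss_g * (1 + 1e-9) + 1e-12) {
    polish <- iterate_psi(x, y, cm, g_psi, lo, hi, tol, max_iter)
    if (polish$converged && rss_at(polish$psi) <= rss_g * (1 + 1e-9)) {
      it <- polish
    } else {
      it <- list(psi = g_psi, converged = FALSE,
                 iterations = it$iterations)
      method <- "grid"
    }
  }
  psi <- it$psi

  # final working fit at the solution (for coefficients, sigma, delta CI)
  wf <- working_fit(x, y, cm, psi)
  cf <- wf$coef
  sigma <- wf$sigma
  se_psi <- if (abs(cf["u"]) > .Machine$double.eps^0.5)
    wf$se["v"] / abs(cf["u"]) else 0
  if (!is.finite(se_psi)) se_psi <- 0
  tq <- stats::qt(1 - (1 - level) / 2, df = max(1, n - length(cf)))
  delta_ci <- psi + c(-1, 1) * tq * se_psi

  prof_ci <- function() {
    n_par <- 4 + if (is.null(cm)) 0 else ncol(cm)
    thr <- rss_g * (1 + stats::qf(level, 1, n - n_par) / (n - n_par))
    inside <- pr$grid[pr$rss <= thr]
    c(min(inside), max(inside))
  }
  fit_ci <- switch(ci,
    delta = delta_ci,
    profile = prof_ci(),
    boot = boot_ci_psi(x, y, cm, psi, n_boot, boot_seed, lo, hi, grid_step,
                       tol, max_iter, level),
    hybrid = {
      pci <- prof_ci()
      c(min(delta_ci[1], pci[1]), max(delta_ci[2], pci[2]))
    })
  fit_ci <- c(max(fit_ci[1], min(x)), min(fit_ci[2], max(x)))

  U <- pmax(0, x - psi)
  X <- cbind(1, x, U, cm)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0          # aliased (e.g. constant) covariates
  fitted <- as.numeric(X %*% beta)

  structure(list(
    psi = psi, ci = fit_ci,
    ci_method = switch(ci, boot = "bootstrap-ci", ci),
    slope_left = unname(beta[2]), slope_right = unname(beta[2] + beta[3]),
    intercept = unname(beta[1]),
    coefficients = c(intercept = unname(beta[1]), x = unname(beta[2]),
                     slope_change = unname(beta[3]),
                     if (!is.null(cm))
                       stats::setNames(unname(beta[-(1:3)]), colnames(cm))),
    n = n, sigma = sigma, level = level,
    converged = it$converged, iterations = it$iterations, method = method,
    fitted.values = fitted, residuals = y - fitted,
    x = x, y = y, covariates = cm,
    call = match.call()), class = "piecewise_fit")
}

# One pass of the Muggeo-style iteration. Returns psi, convergence flag.
iterate_psi <- function(x, y, cm, psi0, lo, hi, tol, max_iter) {
  psi <- psi0
  for (i in seq_len(max_iter)) {
    wf <- working_fit(x, y, cm, psi)
    b2 <- wf$coef["u"]; g <- wf$coef["v"]
    if (!is.finite(b2) || !is.finite(g) ||
        abs(b2) < .Machine$double.eps^0.5)
      return(list(psi = psi, converged = FALSE, iterations = i))
    new_psi <- psi - g / b2
    if (new_psi <= lo || new_psi >= hi)
      return(list(psi = unname(min(max(new_psi, lo), hi)),
                  converged = FALSE, iterations = i))
    if (abs(new_psi - psi) < tol)
      return(list(psi = unname(new_psi), converged = TRUE, iterations = i))
    psi <- unname(new_psi)
  }
  list(psi = psi, converged = FALSE, iterations = max_iter)
}

# Working model y ~ 1 + x + (x-psi)+ + I(x>psi) + covariates.
working_fit <- function(x, y, cm, psi) {
  U <- pmax(0, x - psi)
  V <- as.numeric(x > psi)
  X <- cbind(`(i)` = 1, x = x, u = U, v = V, cm)
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% ifelse(is.na(beta), 0, beta)
  df <- length(y) - qr_x$rank
  s2 <- if (df > 0) sum(res^2) / df else 0
  xtxi <- tryCatch(chol2inv(qr.R(qr_x)), error = function(e) NULL)
  se <- if (is.null(xtxi)) rep(NA_real_, ncol(X))
        else sqrt(pmax(0, diag(xtxi)) * s2)
  names(se) <- colnames(X)
  list(coef = stats::setNames(as.numeric(beta), colnames(X)),
       se = se, sigma = sqrt(s2))
}

# RSS profile over candidate breakpoints.
profile_rss <- function(x, y, cm, lo, hi, step) {
  grid <- seq(lo, hi, by = step)
  rss <- vapply(grid, function(p) {
    X <- cbind(1, x, pmax(0, x - p), cm)
    sum(stats::lm.fit(X, y)$residuals^2)
  }, numeric(1))
  list(grid = grid, rss = rss)
}

# Grid search over candidate breakpoints (RSS-minimising psi).
grid_psi <- function(x, y, cm, lo, hi, step) {
  pr <- profile_rss(x, y, cm, lo, hi, step)
  list(psi = pr$grid[which.min(pr$rss)], converged = TRUE,
       iterations = length(pr$grid))
}

boot_ci_psi <- function(x, y, cm, psi_hat, n_boot, seed, lo, hi, step,
                        tol, max_iter, level) {
  set.seed(as.integer(seed))
  n <- length(x)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    cmb <- if (is.null(cm)) NULL else cm[i, , drop = FALSE]
    it <- iterate_psi(x[i], y[i], cmb, psi_hat,
                      min(x[i]) + step, max(x[i]) - step, tol, max_iter)
    if (!it$converged)
      it <- grid_psi(x[i], y[i], cmb, min(x[i]) + step, max(x[i]) - step,
                     step)
    it$psi
  }, numeric(1))
  unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Two-segment regression (", x$method, ")\n", sep = "")
  cat(sprintf("  breakpoint psi = %.3f  [%.3f, %.3f] (%d%% %s CI)\n",
              x$psi, x$ci[1], x$ci[2], round(100 * x$level), x$ci_method))
  cat(sprintf("  slopes: %.4f (below) | %.4f (above);  n = %d, sigma = %.4g\n",
              x$slope_left, x$slope_right, x$n, x$sigma))
  invisible(x)
}

#' @export
summary.piecewise_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.piecewise_fit")
}

#' @export
print.summary.piecewise_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCoefficients:\n")
  print(round(f$coefficients, 5))
  cat(sprintf("\nconverged: %s after %d iterations\n",
              f$converged, f$iterations))
  invisible(x)
}

#' @export
coef.piecewise_fit <- function(object, ...) object$coefficients

#' @export
residuals.piecewise_fit <- function(object, ...) object$residuals

#' @export
fitted.piecewise_fit <- function(object, ...) object$fitted.values

# Gaussian profile log-likelihood from an RSS. Near-exact fits are floored
# at a relative tolerance of the response scale so that floating-point dust
# in a saturated model cannot register as likelihood gain.
gauss_loglik <- function(rss, n, scale) {
  floor_rss <- max(1e-12 * scale, .Machine$double.xmin)
  -n / 2 * (log(2 * pi) + log(max(rss, floor_rss) / n) + 1)
}

#' @export
logLik.piecewise_fit <- function(object, ...) {
  n <- object$n
  ll <- gauss_loglik(sum(object$residuals^2), n,
                     sum((object$y - mean(object$y))^2))
  # parameters: regression coefficients + breakpoint + residual variance
  structure(ll, df = length(object$coefficients) + 2, nobs = n,
            class = "logLik")
}

#' @export
confint.piecewise_fit <- function(object, parm = "psi", level = 0.95, ...) {
  m <- matrix(object$ci, nrow = 1,
              dimnames = list("psi", c("low", "high")))
  m
}

#' Predict from a two-segment fit
#'
#' @param object A `piecewise_fit`.
#' @param newdata Optional data frame with column `x` (and any covariates
#'   used in the fit); defaults to the training data.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.piecewise_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  x <- newdata$x
  X <- cbind(1, x, pmax(0, x - object$psi))
  cf <- object$coefficients
  if (length(cf) > 3) {
    cn <- names(cf)[-(1:3)]
    X <- cbind(X, as.matrix(newdata[, cn, drop = FALSE]))
  }
  as.numeric(X %*% cf)
}

#' Simulate responses from a fitted two-segment model
#'
#' @param object A `piecewise_fit`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated y at the training x.
#' @export
simulate.piecewise_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim,
    mu + stats::rnorm(length(mu), 0, object$sigma), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Plot a two-segment fit
#'
#' Scatter of the data with the fitted segments, the breakpoint (solid
#' vertical line) and its confidence interval (dashed lines).
#'
#' @param x A `piecewise_fit`.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.piecewise_fit <- function(x, xlab = "ambient temperature (degC)",
                               ylab = "response", ...) {
  graphics::plot(x$x, x$y, xlab = xlab, ylab = ylab, pch = 19,
                 col = grDevices::grey(0.4), ...)
  ox <- order(x$x)
  nd <- data.frame(x = x$x[ox])
  if (!is.null(x$covariates)) {
    for (cn in colnames(x$covariates))
      nd[[cn]] <- mean(x$covariates[, cn])
  }
  graphics::lines(nd$x, predict(x, nd), lwd = 2)
  graphics::abline(v = x$psi, lwd = 2)
  graphics::abline(v = x$ci, lty = 2)
  invisible(x)
}

#' Test for the absence of a breakpoint
#'
#' Compares a plain linear model with the two-segment model by small-sample
#' AICc. The breakpoint is declared supported only when the two-segment
#' model improves AICc by at least `delta_rule` (default 2); used to confirm
#' that oxygen consumption shows no upper inflection at high ambient
#' temperatures.
#'
#' @inheritParams fit_piecewise
#' @param delta_rule Required AICc improvement. Default 2.
#' @return List with `aicc_linear`, `aicc_segmented`, `delta_aicc`
#'   (linear minus segmented), `verdict` ("breakpoint-supported" or
#'   "no-breakpoint") and the two fits.
#' @examples
#' d <- generate_breakpoint_dataset(30, c(-0.5, -0.5), 16, c(20, 40),
#'                                  n = 30, noise_sd = 0.1, seed = 2)
#' test_no_breakpoint(d$x, d$y)$verdict
#' @export
test_no_breakpoint <- function(x, y, covariates = NULL, delta_rule = 2,
                               grid_step = 0.05) {
  keep <- stats::complete.cases(x, y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  cm <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X <- cbind(1, x, cm)
  lf <- stats::lm.fit(X, y)
  scale <- sum((y - mean(y))^2)
  ll_lin <- gauss_loglik(sum(lf$residuals^2), n, scale)
  k_lin <- ncol(X) + 1                 # coefficients + residual variance
  seg <- fit_piecewise(x, y, covariates = covariates, grid_step = grid_step)
  ll_seg <- as.numeric(logLik(seg))
  k_seg <- length(seg$coefficients) + 2  # + breakpoint + residual variance
  a_lin <- aicc(ll_lin, k_lin, n)
  a_seg <- aicc(ll_seg, k_seg, n)
  delta <- a_lin - a_seg
  list(aicc_linear = a_lin, aicc_segmented = a_seg, delta_aicc = delta,
       verdict = if (delta >= delta_rule) "breakpoint-supported"
                 else "no-breakpoint",
       linear_loglik = ll_lin, segmented_fit = seg)
}

#' Breakpoint fits for the four thermal responses
#'
#' Fits two-segment regressions of the retained resting bouts' responses
#' against measured ambient temperature: VO2 (with body mass as covariate;
#' its breakpoint is the lower critical temperature), evaporative water loss,
#' subcutaneous temperature, and EHL/MHP. The absence of an upper VO2
#' inflection is checked with [test_no_breakpoint()] on the subset at
#' ambient temperatures >= 30 degC.
#'
#' @param bouts Bout table from [extract_rmr()] (rows with `retained = TRUE`
#'   are used; pass pre-filtered tables unchanged).
#' @param min_n Minimum retained bouts per response. Default 8.
#' @param grid_step Breakpoint grid resolution. Default 0.05.
#' @return Object of class `response_suite`: a list with elements `vo2`,
#'   `ewl`, `tsub`, `ehl_mhp` (each a [fit_piecewise()] result or a skip
#'   record) and `vo2_upper` (the no-upper-breakpoint comparison).
#' @export
fit_response_suite <- function(bouts, min_n = 8, grid_step = 0.05) {
  b <- bouts[bouts$retained, , drop = FALSE]
  resp <- list(vo2 = b$vo2, ewl = b$vh2o, tsub = b$t_sub,
               ehl_mhp = b$ehl_mhp)
  use_mass <- !all(is.na(b$mass_g)) && length(unique(b$mass_g)) > 1
  out <- list()
  for (nm in names(resp)) {
    yy <- resp[[nm]]
    ok <- is.finite(yy) & is.finite(b$ta_measured)
    if (sum(ok) < min_n) {
      out[[nm]] <- list(skipped = TRUE,
                        reason = paste0("only ", sum(ok),
                                        " retained bouts (need ", min_n, ")"))
      next
    }
    cov <- if (nm == "vo2" && use_mass)
      data.frame(mass_g = b$mass_g[ok]) else NULL
    out[[nm]] <- fit_piecewise(b$ta_measured[ok], yy[ok], covariates = cov,
                               grid_step = grid_step)
  }
  hi <- b$ta_measured >= 30 & is.finite(b$vo2)
  out$vo2_upper <- if (sum(hi) >= min_n) {
    test_no_breakpoint(b$ta_measured[hi], b$vo2[hi],
                       covariates = if (use_mass)
                         data.frame(mass_g = b$mass_g[hi]) else NULL,
                       grid_step = grid_step)
  } else list(skipped = TRUE, reason = "fewer than 8 bouts at Ta >= 30")
  class(out) <- "response_suite"
  out
}

#' @export
print.response_suite <- function(x, ...) {
  lab <- c(vo2 = "VO2 (lower critical temperature)",
           ewl = "Evaporative water loss",
           tsub = "Subcutaneous temperature",
           ehl_mhp = "EHL/MHP")
  cat("Thermal response breakpoints\n")
  for (nm in names(lab)) {
    f <- x[[nm]]
    if (is.null(f)) next
    if (!is.null(f$skipped)) {
      cat(sprintf("  %-36s skipped: %s\n", lab[nm], f$reason))
    } else {
      cat(sprintf("  %-36s psi = %.2f [%.2f, %.2f] degC\n",
                  lab[nm], f$psi, f$ci[1], f$ci[2]))
    }
  }
  if (!is.null(x$vo2_upper$verdict))
    cat("  Upper VO2 inflection (Ta >= 30):    ", x$vo2_upper$verdict,
        sprintf(" (dAICc = %.2f)\n", x$vo2_upper$delta_aicc))
  invisible(x)
}
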