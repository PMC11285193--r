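#' Construct / validate a respirometry trace
#'
#' A respirometry trace is a data frame with one row per analyzer sample and
#' columns `time` (s since trial start), excurrent fractions `fe_o2`,
#' `fe_co2`, `fe_h2o`, incurrent fractions `fi_o2`, `fi_co2`, `fi_h2o`,
#' `flow` (ml min^-1 STP incurrent), `t_chamber` (degC), `t_sub` (degC, may
#' be NA) and an optional `marker` column.
#'
#' @param df Data frame holding the columns above.
#' @param hz Sampling rate in Hz, stored as an attribute.
#' @return The validated data frame with class `respirometry_trace`.
#' @export
respirometry_trace <- function(df, hz = 2) {
  req <- c("time", "fe_o2", "fe_co2", "fe_h2o",
           "fi_o2", "fi_co2", "fi_h2o", "flow", "t_chamber", "t_sub")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("trace format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"marker" %in% names(df)) df$marker <- NA_character_
  if (is.unsorted(df$time, strictly = TRUE))
    stop("trace integrity error: time must be strictly increasing",
         call. = FALSE)
  fr <- c("fe_o2", "fe_co2", "fe_h2o", "fi_o2", "fi_co2", "fi_h2o")
  for (k in fr)
    if (any(df[[k]] < 0 | df[[k]] >= 1, na.rm = TRUE))
      stop("trace integrity error: ", k, " outside [0, 1)", call. = FALSE)
  if (any(df$fe_o2 + df$fe_co2 + df$fe_h2o >= 1, na.rm = TRUE))
    stop("trace integrity error: excurrent fractions sum to >= 1",
         call. = FALSE)
  if (any(df$flow <= 0, na.rm = TRUE))
    stop("trace integrity error: flow must be > 0", call. = FALSE)
  attr(df, "hz") <- hz
  class(df) <- c("respirometry_trace", "data.frame")
  df
}

# Piecewise forward model: true steady-state rates at ambient temperature ta.
# Units: vo2 ml O2 h^-1, vco2 ml CO2 h^-1, ewl mg H2O h^-1, tsub degC.
forward_rates <- function(params, ta) {
  vo2 <- params$bmr - params$slope_below_lct * pmax(0, params$lct - ta)
  list(vo2 = vo2,
       vco2 = params$rq * vo2,
       ewl = params$ewl_base +
         params$ewl_slope_above * pmax(0, ta - params$psi_ewl),
       tsub = params$tsub_base +
         params$tsub_slope_above * pmax(0, ta - params$psi_tsub))
}

# mg of water per ml of vapour at STP (0 degC, 101.325 kPa)
MG_PER_ML_H2O <- 0.803

#' Simulate one flow-through respirometry trial
#'
#' Generates an analyzer trace for a single animal exposed to a rising
#' staircase of ambient temperatures, together with the ground truth needed
#' to test the extraction pipeline. The steady-state physiology follows a
#' Scholander–Irving piecewise model (see [physiology_params()]); activity
#' bursts multiply VO2/VCO2; chamber washout low-pass filters what the
#' analyzers see; excurrent fractions are computed by exact mass balance so
#' that, at zero noise, [rates_from_fractions()] inverts the generator
#' exactly.
#'
#' @param params [physiology_params()].
#' @param schedule Two-column matrix or data frame: ambient temperature
#'   (degC, non-decreasing) and duration (minutes) of each step.
#' @param seed Integer RNG seed.
#' @param hz Sampling rate, Hz. Default 2.
#' @param flow Incurrent flow, ml min^-1. Default 1000.
#' @param fi_o2,fi_co2,fi_h2o Incurrent fractions. Defaults 0.2095, 0.0004,
#'   0.005.
#' @param washout_tau Chamber washout time constant, seconds (0 disables the
#'   filter). Default 300.
#' @param chamber_tau Thermal lag of the chamber air, seconds. Default 120.
#' @param noise_sd Analyzer white noise SD on each excurrent fraction.
#'   Default 2e-5.
#' @param activity Logical: insert activity bursts? Default TRUE.
#' @param burst_factor Multiplier on VO2/VCO2 during a burst. Default 2.5.
#' @param burst_rate_per_h Mean number of bursts per hour. Default 2.
#' @param tsub_noise_sd White noise on the subcutaneous channel, degC
#'   (0 when `noise_sd` is 0). Default 0.05.
#' @param settle_in_s Settle-in period used when locating plantable resting
#'   windows in the ground truth. Default 3600.
#' @return A list with elements `trace` (a [respirometry_trace()]) and
#'   `truth` (list: per-sample true rates, activity intervals, per-step
#'   table of true resting values, planted resting windows).
#' @examples
#' sim <- generate_respirometry_trial(physiology_params(),
#'   schedule = cbind(c(25, 30), c(45, 45)), seed = 1)
#' nrow(sim$trace)
#' @export
generate_respirometry_trial <- function(params, schedule, seed,
                                        hz = 2, flow = 1000,
                                        fi_o2 = 0.2095, fi_co2 = 0.0004,
                                        fi_h2o = 0.005,
                                        washout_tau = 300, chamber_tau = 120,
                                        noise_sd = 2e-5,
                                        activity = TRUE, burst_factor = 2.5,
                                        burst_rate_per_h = 2,
                                        tsub_noise_sd = 0.05,
                                        settle_in_s = 3600) {
  stopifnot(inherits(params, "physiology_params"))
  schedule <- as.matrix(schedule)
  if (ncol(schedule) != 2) stop("schedule must have two columns (Ta, minutes)")
  ta_steps <- schedule[, 1]; mins <- schedule[, 2]
  if (any(diff(ta_steps) < 0))
    stop("contract error: schedule temperatures must be non-decreasing",
         call. = FALSE)
  if (any(mins <= 0)) stop("step durations must be > 0", call. = FALSE)
  if (washout_tau < 0)
    stop("contract error: washout_tau must be >= 0 (0 disables washout)",
         call. = FALSE)
  set.seed(as.integer(seed))

  dt <- 1 / hz
  n_per <- round(mins * 60 * hz)
  n <- sum(n_per)
  time <- (seq_len(n) - 1) * dt
  step_id <- rep(seq_along(ta_steps), n_per)
  ta_set <- ta_steps[step_id]
  step_start <- c(0, cumsum(n_per))[seq_along(ta_steps)] * dt
  step_end <- cumsum(n_per) * dt

  # chamber air temperature lags the set point
  t_chamber <- lowpass(ta_set, dt, chamber_tau)

  phys <- forward_rates(params, t_chamber)

  # activity bursts: Poisson onsets, 1-5 min duration
  act <- matrix(numeric(0), ncol = 2)
  mult <- rep(1, n)
  if (activity && burst_rate_per_h > 0) {
    n_burst <- stats::rpois(1, burst_rate_per_h * (n * dt) / 3600)
    if (n_burst > 0) {
      on <- sort(stats::runif(n_burst, 0, n * dt))
      dur <- stats::runif(n_burst, 60, 300)
      act <- cbind(on, pmin(on + dur, n * dt))
      for (b in seq_len(nrow(act))) {
        idx <- time >= act[b, 1] & time < act[b, 2]
        mult[idx] <- burst_factor
      }
    }
  }

  vo2_true <- phys$vo2 * mult            # ml h^-1
  vco2_true <- phys$vco2 * mult
  vh2o_true <- phys$ewl                  # mg h^-1

  # what the analyzers see after chamber washout
  vo2_a <- lowpass(vo2_true, dt, washout_tau)
  vco2_a <- lowpass(vco2_true, dt, washout_tau)
  vh2o_a <- lowpass(vh2o_true, dt, washout_tau)

  # exact mass balance, per-minute units
  vo2_m <- vo2_a / 60
  vco2_m <- vco2_a / 60
  vh2o_m <- vh2o_a / 60 / MG_PER_ML_H2O  # ml vapour min^-1
  outflow <- flow - vo2_m + vco2_m + vh2o_m
  fe_o2 <- (flow * fi_o2 - vo2_m) / outflow
  fe_co2 <- (flow * fi_co2 + vco2_m) / outflow
  fe_h2o <- (flow * fi_h2o + vh2o_m) / outflow

  if (noise_sd > 0) {
    fe_o2 <- fe_o2 + stats::rnorm(n, 0, noise_sd)
    fe_co2 <- pmax(fe_co2 + stats::rnorm(n, 0, noise_sd), 0)
    fe_h2o <- pmax(fe_h2o + stats::rnorm(n, 0, noise_sd), 0)
  }
  t_sub <- phys$tsub +
    if (noise_sd > 0) stats::rnorm(n, 0, tsub_noise_sd) else 0

  trace <- respirometry_trace(data.frame(
    time = time, fe_o2 = fe_o2, fe_co2 = fe_co2, fe_h2o = fe_h2o,
    fi_o2 = fi_o2, fi_co2 = fi_co2, fi_h2o = fi_h2o,
    flow = flow, t_chamber = t_chamber, t_sub = t_sub,
    marker = NA_character_), hz = hz)
  attr(trace, "seed") <- as.integer(seed)
  attr(trace, "mass_g") <- params$mass_g

  rest <- forward_rates(params, ta_steps)
  steps <- data.frame(step = seq_along(ta_steps), ta_set = ta_steps,
                      start_s = step_start, end_s = step_end,
                      vo2_true = rest$vo2, vco2_true = rest$vco2,
                      ewl_true = rest$ewl, tsub_true = rest$tsub)

  truth <- list(
    rates = data.frame(time = time, vo2 = vo2_true, vco2 = vco2_true,
                       vh2o = vh2o_true),
    activity = if (nrow(act)) data.frame(start_s = act[, 1], end_s = act[, 2])
               else data.frame(start_s = numeric(0), end_s = numeric(0)),
    steps = steps,
    resting_windows = quiet_spans(act, steps, settle_in_s, n * dt),
    seed = as.integer(seed))
  list(trace = trace, truth = truth)
}

# discrete first-order low-pass filter; tau = 0 means pass-through
lowpass <- function(x, dt, tau) {
  if (tau <= 0) return(x)
  a <- exp(-dt / tau)
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive",
                           init = x[1]))
}

# contiguous spans >= 300 s free of activity, after settle-in, per step
quiet_spans <- function(act, steps, settle_in_s, t_end) {
  out <- list()
  for (i in seq_len(nrow(steps))) {
    lo <- max(steps$start_s[i], settle_in_s)
    hi <- steps$end_s[i]
    if (hi - lo < 300) next
    edges <- c(lo, hi)
    if (nrow(act)) {
      keep <- act[act[, 2] > lo & act[, 1] < hi, , drop = FALSE]
      cur <- lo
      spans <- NULL
      ord <- order(keep[, 1])
      for (b in ord) {
        if (keep[b, 1] > cur) spans <- rbind(spans, c(cur, keep[b, 1]))
        cur <- max(cur, keep[b, 2])
      }
      if (cur < hi) spans <- rbind(spans, c(cur, hi))
    } else spans <- matrix(c(lo, hi), ncol = 2)
    if (is.null(spans)) next
    spans <- spans[spans[, 2] - spans[, 1] >= 300, , drop = FALSE]
    if (nrow(spans))
      out[[length(out) + 1]] <- data.frame(step = steps$step[i],
                                           start_s = spans[, 1],
                                           end_s = spans[, 2])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(step = integer(0), start_s = numeric(0),
                  end_s = numeric(0))
}

#' Simulate data from a two-segment linear model
#'
#' Draws (x, y) pairs from
#' `y = intercept + b1*x + (b2 - b1)*max(0, x - psi) + N(0, noise_sd)`,
#' the data-generating model assumed by [fit_piecewise()].
#'
#' @param psi True breakpoint; must lie inside `x_range`.
#' @param slopes Length-2 numeric, slopes below and above the breakpoint.
#' @param intercept Intercept of the left segment.
#' @param x_range Length-2 numeric range of x.
#' @param n Number of points (>= 8).
#' @param noise_sd Residual SD.
#' @param seed Integer RNG seed.
#' @param grid Logical: place x on a regular grid instead of uniform draws.
#' @return Data frame with columns `x`, `y`.
#' @examples
#' d <- generate_breakpoint_dataset(30, c(-0.5, 0), 16, c(20, 40), 20, 0, 1)
#' fit_piecewise(d$x, d$y)$psi
#' @export
generate_breakpoint_dataset <- function(psi, slopes, intercept, x_range,
                                        n, noise_sd, seed, grid = FALSE) {
  stopifnot(length(slopes) == 2, length(x_range) == 2)
  if (n < 8) stop("contract error: n must be >= 8", call. = FALSE)
  if (psi <= min(x_range) || psi >= max(x_range))
    stop("contract error: psi must lie strictly inside x_range",
         call. = FALSE)
  set.seed(as.integer(seed))
  x <- if (grid) seq(x_range[1], x_range[2], length.out = n)
       else stats::runif(n, x_range[1], x_range[2])
  y <- intercept + slopes[1] * x +
    (slopes[2] - slopes[1]) * pmax(0, x - psi) +
    stats::rnorm(n, 0, noise_sd)
  data.frame(x = x, y = y)
}

#' Simulate paired subcutaneous and core temperature readings
#'
#' Emulates simultaneous PIT-tag (subcutaneous) and implanted-logger (core)
#' measurements, where the subcutaneous channel systematically underestimates
#' core temperature.
#'
#' @param n Number of pairs.
#' @param offset Mean of (t_sub - t_core), degC. Default -0.72.
#' @param sd SD of the offset across pairs, degC. Default 0.25.
#' @param core_mean,core_sd Distribution of core temperature, degC.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `t_sub`, `t_core`.
#' @export
generate_paired_temps <- function(n, offset = -0.72, sd = 0.25,
                                  core_mean = 37.5, core_sd = 0.6, seed = 1) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  t_core <- stats::rnorm(n, core_mean, core_sd)
  data.frame(t_sub = t_core + offset + stats::rnorm(n, 0, sd),
             t_core = t_core)
}

#' Per-trial biological variation of physiology parameters
#'
#' Draws an individual trial's parameters around population defaults: body
#' mass normal (sd 8.1 g), metabolic and evaporative levels log-normal with a
#' given coefficient of variation and allometric mass scaling (exponent
#' 0.75), and a small additive shift on the subcutaneous baseline. Breakpoint
#' locations are population-level and are not jittered.
#'
#' @param params Population [physiology_params()].
#' @param seed Integer RNG seed.
#' @param cv Coefficient of variation of bmr and ewl_base. Default 0.08.
#' @param mass_sd SD of body mass, g. Default 8.1.
#' @return A new `physiology_params` object.
#' @export
jitter_physiology <- function(params, seed, cv = 0.08, mass_sd = 8.1) {
  set.seed(as.integer(seed))
  mass <- max(30, stats::rnorm(1, params$mass_g, mass_sd))
  scale <- (mass / params$mass_g)^0.75
  sdl <- sqrt(log(1 + cv^2))
  physiology_params(
    bmr = params$bmr * scale * stats::rlnorm(1, -sdl^2 / 2, sdl),
    lct = params$lct,
    slope_below_lct = params$slope_below_lct * scale *
      stats::rlnorm(1, -sdl^2 / 2, sdl),
    ewl_base = params$ewl_base * scale * stats::rlnorm(1, -sdl^2 / 2, sdl),
    psi_ewl = params$psi_ewl,
    ewl_slope_above = params$ewl_slope_above * scale,
    tsub_base = params$tsub_base + stats::rnorm(1, 0, 0.3),
    psi_tsub = params$psi_tsub,
    tsub_slope_above = params$tsub_slope_above,
    rq = params$rq, mass_g = mass)
}
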