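#' Modal temperature on a fixed bin grid
#'
#' Mode computed by binning to `bin`-degree cells (default 0.1 degC, the
#' logger resolution scale); ties are broken toward the lower bin centre.
#'
#' @param x Numeric vector.
#' @param bin Bin width, degC. Default 0.1.
#' @return The modal bin centre.
#' @export
mode_binned <- function(x, bin = 0.1) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  centers <- round(x / bin) * bin
  tab <- table(centers)
  best <- names(tab)[tab == max(tab)]
  min(as.numeric(best))
}

#' Remove the deployment settling week and lab visits
#'
#' Drops all records within the first 7 days of deployment and any records
#' inside lab-visit intervals (e.g. respirometry sessions).
#'
#' @param tb Data frame with `timestamp`, `temperature`.
#' @param lab_visits Optional data frame with `start`, `end` (POSIXct).
#' @param deployment_start POSIXct; defaults to the first timestamp.
#' @return The filtered data frame (with a warning if nothing is left).
#' @export
preprocess_deployment <- function(tb, lab_visits = NULL,
                                  deployment_start = min(tb$timestamp)) {
  keep <- tb$timestamp >= deployment_start + 7 * 86400
  if (!is.null(lab_visits) && nrow(lab_visits)) {
    for (i in seq_len(nrow(lab_visits)))
      keep <- keep & !(tb$timestamp >= lab_visits$start[i] &
                         tb$timestamp < lab_visits$end[i])
  }
  out <- tb[keep, , drop = FALSE]
  if (!nrow(out))
    warning("no records remain after deployment filtering", call. = FALSE)
  out
}

#' Match body-temperature records to the nearest ambient record
#'
#' Nearest-neighbour join in time. Pairs farther apart than `max_gap_min`
#' minutes get a missing ambient value; ties go to the earlier record.
#'
#' @param tb Data frame `timestamp`, `temperature` (body).
#' @param ta Data frame `timestamp`, `temperature` (ambient).
#' @param max_gap_min Maximum allowed gap, minutes. Default 45.
#' @return `tb` with a `t_a` column added.
#' @export
match_ambient <- function(tb, ta, max_gap_min = 45) {
  if (is.null(ta) || !nrow(ta)) {
    warning("empty ambient series; all matches missing", call. = FALSE)
    tb$t_a <- NA_real_
    return(tb)
  }
  o <- order(ta$timestamp)
  tt <- as.numeric(ta$timestamp[o])
  tv <- ta$temperature[o]
  tn <- as.numeric(tb$timestamp)
  k <- findInterval(tn, tt)
  lo <- pmax(k, 1)
  hi <- pmin(k + 1, length(tt))
  dlo <- abs(tn - tt[lo])
  dhi <- abs(tt[hi] - tn)
  pick <- ifelse(k == 0, hi, ifelse(dlo <= dhi, lo, hi))  # tie -> earlier
  gap <- abs(tn - tt[pick])
  t_a <- tv[pick]
  t_a[gap > max_gap_min * 60] <- NA_real_
  tb$t_a <- t_a
  tb
}

#' Build a phase-labelled thermal profile
#'
#' Joins body and ambient series, assigns day/night phase by the site's
#' sunrise/sunset, and attaches dusk-to-dusk squirrel dates.
#'
#' @param tb Body-temperature data frame (`timestamp`, `temperature`).
#' @param ta Ambient data frame or NULL.
#' @param site A [site()].
#' @param individual Identifier.
#' @return Data frame of class `thermal_profile`: `individual`, `timestamp`,
#'   `t_b`, `t_a`, `phase`, `squirrel_date`.
#' @examples
#' f <- generate_free_ranging(rhythm_params(noise_sd = 0), site(), 3, 1)
#' p <- thermal_profile(f$tb, f$ta, site())
#' table(p$phase)
#' @export
thermal_profile <- function(tb, ta = NULL, site, individual = "sq1") {
  ph <- solar_phase(tb$timestamp, site)
  sqd <- assign_squirrel_date(tb$timestamp, site)
  m <- if (!is.null(ta)) match_ambient(tb, ta)$t_a else NA_real_
  out <- data.frame(individual = individual, timestamp = tb$timestamp,
                    t_b = tb$temperature, t_a = m,
                    phase = ph$phase, squirrel_date = sqd)
  class(out) <- c("thermal_profile", "data.frame")
  out
}

#' Per squirrel-date and phase summary statistics
#'
#' For each (individual, squirrel date, phase): modal, mean, SD (n-1
#' denominator), minimum, maximum and range of body temperature and of the
#' matched ambient temperature, plus record count. A companion per-day table
#' gives the whole-day max - min.
#'
#' @param profile A [thermal_profile()].
#' @param mode_bin Bin width for modes, degC. Default 0.1.
#' @return List with `phases` (per individual x squirrel_date x phase rows)
#'   and `days` (per individual x squirrel_date: whole-day min, max, range).
#' @export
phase_summaries <- function(profile, mode_bin = 0.1) {
  stat <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x))
      return(c(mode = NA_real_, mean = NA_real_, sd = NA_real_,
               min = NA_real_, max = NA_real_, range = NA_real_))
    c(mode = mode_binned(x, mode_bin), mean = mean(x),
      sd = if (length(x) > 1) stats::sd(x) else 0,
      min = min(x), max = max(x), range = max(x) - min(x))
  }
  grp_stats <- function(idx_list, col) {
    t(vapply(idx_list, function(i) stat(profile[[col]][i]), numeric(6)))
  }
  key <- interaction(profile$individual, as.character(profile$squirrel_date),
                     profile$phase, drop = TRUE)
  idx <- split(seq_len(nrow(profile)), key)
  first <- vapply(idx, `[`, integer(1), 1)
  sb <- grp_stats(idx, "t_b")
  sa <- grp_stats(idx, "t_a")
  phases <- data.frame(
    individual = profile$individual[first],
    squirrel_date = profile$squirrel_date[first],
    phase = profile$phase[first],
    n_records = lengths(idx),
    mode_tb = sb[, 1], mean_tb = sb[, 2], sd_tb = sb[, 3],
    min_tb = sb[, 4], max_tb = sb[, 5], range_tb = sb[, 6],
    mode_ta = sa[, 1], mean_ta = sa[, 2], sd_ta = sa[, 3],
    min_ta = sa[, 4], max_ta = sa[, 5], range_ta = sa[, 6],
    row.names = NULL)
  dkey <- interaction(profile$individual,
                      as.character(profile$squirrel_date), drop = TRUE)
  didx <- split(seq_len(nrow(profile)), dkey)
  dfirst <- vapply(didx, `[`, integer(1), 1)
  dmin <- vapply(didx, function(i) min(profile$t_b[i]), numeric(1))
  dmax <- vapply(didx, function(i) max(profile$t_b[i]), numeric(1))
  days <- data.frame(
    individual = profile$individual[dfirst],
    squirrel_date = profile$squirrel_date[dfirst],
    min_tb = dmin, max_tb = dmax, range_tb = dmax - dmin,
    n_records = lengths(didx), row.names = NULL)
  list(phases = phases, days = days)
}

#' Heterothermy Index
#'
#' Root mean squared deviation of body temperature from the modal body
#' temperature, `HI = sqrt(sum((Tb_mod - Tb_i)^2) / (n - 1))`. Larger values
#' indicate greater thermolability. The reference `tb_mod` defaults to the
#' active-phase modal temperature over the whole deployment.
#'
#' @param tb_series Numeric vector of body temperatures (n >= 2).
#' @param tb_mod Reference modal body temperature, degC.
#' @return The index, degC (>= 0).
#' @examples
#' heterothermy_index(c(37, 38, 39), 39) # sqrt(5/2)
#' @export
heterothermy_index <- function(tb_series, tb_mod) {
  tb_series <- tb_series[is.finite(tb_series)]
  if (length(tb_series) < 2)
    stop("contract error: need at least 2 records", call. = FALSE)
  sqrt(sum((tb_mod - tb_series)^2) / (length(tb_series) - 1))
}

#' Detect shallow torpor bouts
#'
#' Maximal runs of body temperature below `threshold` lasting at least
#' `min_duration` minutes. Gaps in the sampling grid split candidate runs.
#'
#' @param tb Data frame `timestamp`, `temperature` at a nominally uniform
#'   interval.
#' @param threshold Torpor threshold, degC. Default 35.
#' @param min_duration Minimum bout duration, minutes. Default 30.
#' @param interval_min Nominal sampling interval, minutes. Default 5.
#' @return Data frame of bouts: `start`, `end` (timestamps of first/last
#'   sub-threshold sample), `min_tb`, `n_records`.
#' @export
detect_torpor <- function(tb, threshold = 35, min_duration = 30,
                          interval_min = 5) {
  o <- order(tb$timestamp)
  ts <- tb$timestamp[o]; x <- tb$temperature[o]
  below <- x < threshold & is.finite(x)
  # split runs across sampling gaps
  gap_after <- c(diff(as.numeric(ts)) > 1.5 * interval_min * 60, FALSE)
  grp <- cumsum(c(TRUE, diff(below) != 0) | c(FALSE, gap_after[-length(ts)]))
  out <- list()
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (!below[i[1]]) next
    dur <- (length(i)) * interval_min  # n samples cover n * interval
    if (dur < min_duration) next
    out[[length(out) + 1]] <- data.frame(
      start = ts[i[1]], end = ts[i[length(i)]],
      min_tb = min(x[i]), n_records = length(i))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = tb$timestamp[0], end = tb$timestamp[0],
                  min_tb = numeric(0), n_records = integer(0))
}

#' Cosinor estimate of daily rhythm period and amplitude
#'
#' Fits `Tb(t) = M + A * cos(2*pi*(t - phi)/tau)` by least squares, with the
#' period `tau` profiled over a grid (default 0.5 to 1.5 days, step 0.01).
#' Amplitude is reported as peak-to-trough (`2A`). Constant series yield
#' amplitude 0 with an undefined-period flag.
#'
#' @param tb Data frame `timestamp`, `temperature`.
#' @param period_grid Candidate periods, days.
#' @return List: `period` (days), `amplitude` (peak-to-trough, degC),
#'   `mesor`, `acrophase_days`, `period_defined`.
#' @examples
#' t <- seq(0, 3, by = 1 / 288)
#' tb <- data.frame(timestamp = as.POSIXct("2018-06-01", tz = "UTC") +
#'                    t * 86400,
#'                  temperature = 38.7 + 1.2 * cos(2 * pi * t))
#' daily_rhythm(tb)$amplitude # 2.4
#' @export
daily_rhythm <- function(tb, period_grid = seq(0.5, 1.5, by = 0.01)) {
  x <- tb$temperature
  td <- (as.numeric(tb$timestamp) - as.numeric(tb$timestamp[1])) / 86400
  if (stats::sd(x) == 0)
    return(list(period = NA_real_, amplitude = 0, mesor = mean(x),
                acrophase_days = NA_real_, period_defined = FALSE))
  best <- NULL
  for (tau in period_grid) {
    cc <- cos(2 * pi * td / tau); ss <- sin(2 * pi * td / tau)
    f <- stats::lm.fit(cbind(1, cc, ss), x)
    rss <- sum(f$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, tau = tau, beta = f$coefficients)
  }
  a <- sqrt(best$beta[2]^2 + best$beta[3]^2)
  list(period = best$tau, amplitude = unname(2 * a),
       mesor = unname(best$beta[1]),
       acrophase_days = unname(atan2(best$beta[3], best$beta[2]) *
                                 best$tau / (2 * pi)),
       period_defined = TRUE)
}

#' Per squirrel-date rhythm estimates over a sliding window
#'
#' Applies [daily_rhythm()] to a centred 3-day window around each squirrel
#' date with at least one full day of data.
#'
#' @param profile A [thermal_profile()].
#' @param window_days Window width, days. Default 3.
#' @return Data frame: `individual`, `squirrel_date`, `period`, `amplitude`.
#' @export
daily_rhythm_by_date <- function(profile, window_days = 3) {
  out <- list()
  for (ind in unique(profile$individual)) {
    p <- profile[profile$individual == ind, ]
    for (d in sort(unique(p$squirrel_date))) {
      d <- as.Date(d, origin = "1970-01-01")
      lo <- d - (window_days - 1) / 2
      hi <- d + (window_days - 1) / 2 + 1
      w <- p[p$squirrel_date >= lo & p$squirrel_date < hi, ]
      if (nrow(w) < 288) next
      r <- daily_rhythm(data.frame(timestamp = w$timestamp,
                                   temperature = w$t_b))
      out[[length(out) + 1]] <- data.frame(
        individual = ind, squirrel_date = d,
        period = r$period, amplitude = r$amplitude)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(individual = character(0),
                  squirrel_date = as.Date(character(0)),
                  period = numeric(0), amplitude = numeric(0))
}

#' Offset between subcutaneous and core temperature
#'
#' Mean and SD of `(t_sub - t_core)` over simultaneous pairs; negative means
#' the subcutaneous channel underestimates core temperature.
#'
#' @param pairs Data frame with `t_sub`, `t_core` (n >= 2).
#' @return List `mean`, `sd`, `n`.
#' @examples
#' subq_core_offset(data.frame(t_sub = c(36.8, 37.0),
#'                             t_core = c(37.5, 37.7)))
#' @export
subq_core_offset <- function(pairs) {
  d <- pairs$t_sub - pairs$t_core
  d <- d[is.finite(d)]
  if (length(d) < 2)
    stop("contract error: need at least 2 simultaneous pairs", call. = FALSE)
  list(mean = mean(d), sd = stats::sd(d), n = length(d))
}

#' Daily Heterothermy Index table
#'
#' Computes the Heterothermy Index per (individual, squirrel date), using
#' each individual's deployment-wide active-phase modal temperature as the
#' reference.
#'
#' @param profile A [thermal_profile()].
#' @param mode_bin Bin width for the reference mode. Default 0.1.
#' @return Data frame `individual`, `squirrel_date`, `hi`, `tb_mod`.
#' @export
daily_hi <- function(profile, mode_bin = 0.1) {
  out <- list()
  for (ind in unique(profile$individual)) {
    p <- profile[profile$individual == ind, ]
    tb_mod <- mode_binned(p$t_b[p$phase == "night"], mode_bin)
    for (d in sort(unique(p$squirrel_date))) {
      x <- p$t_b[p$squirrel_date == d]
      if (length(x) < 2) next
      out[[length(out) + 1]] <- data.frame(
        individual = ind, squirrel_date = as.Date(d, origin = "1970-01-01"),
        hi = heterothermy_index(x, tb_mod), tb_mod = tb_mod)
    }
  }
  do.call(rbind, out)
}
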