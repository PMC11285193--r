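# smooth 0..1 cosine ramp
ramp01 <- function(u) {
  u <- pmin(1, pmax(0, u))
  (1 - cos(pi * u)) / 2
}

#' Simulate free-ranging body-temperature and ambient logger series
#'
#' Generates a core body-temperature series at 5-min resolution and an
#' ambient series at 45-min resolution for one individual, with the
#' statistical structure the downstream analysis assumes: a nocturnal
#' circadian rhythm (rest plateau by day, active plateau by night, cosine
#' transitions centred on the site's sunrise/sunset), a post-dusk overshoot,
#' a pre-dawn bump and a late-rest dip, AR(1) noise, day-level coupling of
#' the rest plateau to the daily maximum ambient temperature anomaly, a slow
#' day-of-year trend, and rare shallow torpor bouts during the rest phase.
#' Ambient temperature is a diurnal sinusoid (peak 15:00 local) plus an AR(1)
#' day-level weather term and fine noise.
#'
#' Setting `noise_sd = 0` in the rhythm parameters makes the whole generator
#' deterministic apart from torpor placement: AR(1) noise, weather anomalies
#' and analyzer-style fine noise are all switched off so that exactness
#' checks (modes, torpor boundaries) hold sample by sample.
#'
#' @param rhythm [rhythm_params()].
#' @param site A [site()].
#' @param n_days Number of days (>= 2).
#' @param seed Integer RNG seed.
#' @param start_date First calendar date (local). Default "2018-06-15".
#' @param tb_minutes,ta_minutes Sampling intervals, minutes. Defaults 5, 45.
#' @param ta_mean Mean ambient temperature, degC. Default 18.
#' @param ta_amp Half-amplitude of the diurnal ambient cycle, degC.
#'   Default 6.
#' @param ta_weather_sd SD of the AR(1) day-level weather anomaly, degC.
#'   Default 3.
#' @param ta_noise_sd Fine ambient noise SD, degC. Default 0.8.
#' @param individual Identifier carried into the outputs.
#' @param level_offset Individual-level shift of both plateaus, degC.
#'   Default 0.
#' @return List with `tb` (data frame `timestamp`, `temperature`), `ta`
#'   (same), and `truth`: daily table (squirrel_date, day_of_year,
#'   rest_level, active_level, ta_max), torpor bouts (start, end, min_tb:
#'   spans where the deterministic signal is below 35 degC), the solar event
#'   table, and the modal plateau values.
#' @examples
#' f <- generate_free_ranging(rhythm_params(noise_sd = 0), site(),
#'                            n_days = 3, seed = 1)
#' range(f$tb$temperature)
#' @export
generate_free_ranging <- function(rhythm, site, n_days, seed,
                                  start_date = as.Date("2018-06-15"),
                                  tb_minutes = 5, ta_minutes = 45,
                                  ta_mean = 18, ta_amp = 6,
                                  ta_weather_sd = 3, ta_noise_sd = 0.8,
                                  individual = "sq1", level_offset = 0) {
  stopifnot(inherits(rhythm, "rhythm_params"), inherits(site, "site"))
  if (n_days < 2)
    stop("contract error: n_days must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  start_date <- as.Date(start_date)
  deterministic <- rhythm$noise_sd == 0

  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = site$tz)
  n_tb <- n_days * 24 * 60 / tb_minutes
  ts_tb <- t0 + (seq_len(n_tb) - 1) * tb_minutes * 60
  n_ta <- n_days * 24 * 60 / ta_minutes
  ts_ta <- t0 + (seq_len(n_ta) - 1) * ta_minutes * 60

  # solar events covering the span plus a day each side
  dates <- seq(start_date - 1, start_date + n_days + 1, by = "day")
  ev <- solar_events(dates, site)

  # day-level weather anomaly (AR(1) across calendar days)
  nd <- length(dates)
  wlev <- numeric(nd)
  if (!deterministic) {
    innov <- stats::rnorm(nd, 0, ta_weather_sd * sqrt(1 - 0.6^2))
    wlev[1] <- stats::rnorm(1, 0, ta_weather_sd)
    for (i in 2:nd) wlev[i] <- 0.6 * wlev[i - 1] + innov[i]
  }
  names(wlev) <- as.character(dates)
  lev_of <- function(d) wlev[as.character(as.Date(d))]

  # ---- ambient series -------------------------------------------------
  lt_ta <- as.POSIXlt(ts_ta, tz = site$tz)
  hour_ta <- lt_ta$hour + lt_ta$min / 60
  ta_det <- ta_mean + lev_of(as.Date(lt_ta)) +
    ta_amp * cos(2 * pi * (hour_ta - 15) / 24)
  ta <- ta_det
  if (!deterministic) {
    e <- stats::rnorm(n_ta, 0, ta_noise_sd * sqrt(1 - 0.5^2))
    ar <- numeric(n_ta); ar[1] <- stats::rnorm(1, 0, ta_noise_sd)
    for (i in 2:n_ta) ar[i] <- 0.5 * ar[i - 1] + e[i]
    ta <- ta + ar
  }

  # ---- body-temperature deterministic signal --------------------------
  # alternating event sequence: ... sunrise(d), sunset(d), sunrise(d+1) ...
  ev_t <- as.numeric(t(cbind(ev$sunrise, ev$sunset)))
  ev_type <- rep(c("rise", "set"), nrow(ev))
  ev_date <- rep(ev$date, each = 2)

  tn <- as.numeric(ts_tb)
  k <- findInterval(tn, ev_t)
  stopifnot(all(k >= 1), all(k < length(ev_t)))
  prev_t <- ev_t[k]; next_t <- ev_t[k + 1]
  is_night <- ev_type[k] == "set"
  # plateau levels per sample: trend + individual offset + (rest) coupling
  doy0 <- as.integer(strftime(t0, "%j", tz = site$tz))
  sq_date <- as.Date(ifelse(is_night, ev_date[k],
                            ev_date[k] - 1), origin = "1970-01-01")
  cal_day_date <- as.Date(ev_date[k])          # calendar date of the phase
  doy <- as.integer(strftime(ts_tb, "%j", tz = site$tz))
  base_shift <- rhythm$trend_per_day * (doy - doy0) + level_offset
  rest_lev <- rhythm$mode_rest + base_shift +
    rhythm$ambient_coupling * lev_of(cal_day_date)
  act_lev <- rhythm$mode_active + base_shift

  plateau <- ifelse(is_night, act_lev, rest_lev)
  # cosine ramps of width W centred on each event
  w <- rhythm$transition_minutes * 60
  other <- ifelse(is_night, rest_lev, act_lev)
  tb <- plateau
  near_prev <- (tn - prev_t) < w / 2
  tb[near_prev] <- other[near_prev] +
    (plateau[near_prev] - other[near_prev]) *
    ramp01((tn[near_prev] - prev_t[near_prev]) / w + 0.5)
  near_next <- (next_t - tn) < w / 2
  tb[near_next] <- plateau[near_next] +
    (other[near_next] - plateau[near_next]) *
    ramp01((tn[near_next] - next_t[near_next]) / w + 0.5)

  # within-phase structure: dusk overshoot, pre-dawn bump, late-rest dip
  gauss <- function(t, c, s) exp(-0.5 * ((t - c) / s)^2)
  ni <- which(is_night & !near_prev & !near_next)
  di <- which(!is_night & !near_prev & !near_next)
  tb[ni] <- tb[ni] +
    rhythm$bump_dusk * gauss(tn[ni], prev_t[ni] + w / 2 + 45 * 60, 30 * 60) +
    rhythm$bump_dawn * gauss(tn[ni], next_t[ni] - 90 * 60, 30 * 60)
  tb[di] <- tb[di] -
    rhythm$rest_dip *
    gauss(tn[di], prev_t[di] + 0.65 * (next_t[di] - prev_t[di]), 60 * 60)

  # ---- torpor bouts (rest phase only) ---------------------------------
  sq_dates_all <- sort(unique(sq_date))
  torpid_days <- sq_dates_all[stats::runif(length(sq_dates_all)) <
                                rhythm$torpor_prob_per_day]
  for (d in torpid_days) {
    # the rest phase of squirrel date d is the daytime of calendar d + 1
    idx <- which(!is_night & cal_day_date == as.Date(d, "1970-01-01") + 1 &
                   !near_prev & !near_next)
    if (length(idx) < 4) next
    dur <- rhythm$torpor_duration_min * 60
    span <- range(tn[idx])
    if (diff(span) < dur + 2 * 3600) next
    s <- stats::runif(1, span[1] + 3600, span[2] - 3600 - dur)
    sel <- idx[tn[idx] >= s & tn[idx] <= s + dur]
    depth_curve <- tb[sel] - (tb[sel] - rhythm$torpor_depth) *
      sin(pi * (tn[sel] - s) / dur)
    tb[sel] <- pmin(tb[sel], depth_curve)
  }

  tb_det <- tb
  if (!deterministic) {
    e <- stats::rnorm(n_tb, 0,
                      rhythm$noise_sd * sqrt(1 - rhythm$ar_coeff^2))
    ar <- numeric(n_tb)
    ar[1] <- stats::rnorm(1, 0, rhythm$noise_sd)
    for (i in 2:n_tb) ar[i] <- rhythm$ar_coeff * ar[i - 1] + e[i]
    tb <- tb + ar
  }

  # ---- ground truth ---------------------------------------------------
  below <- tb_det < 35
  bouts <- run_spans(below)
  torpor_tbl <- if (nrow(bouts)) {
    data.frame(start = ts_tb[bouts$start], end = ts_tb[bouts$end],
               min_tb = vapply(seq_len(nrow(bouts)), function(i)
                 min(tb_det[bouts$start[i]:bouts$end[i]]), numeric(1)))
  } else data.frame(start = ts_tb[0], end = ts_tb[0], min_tb = numeric(0))

  sqd <- sq_dates_all
  ta_sq_date <- assign_squirrel_date(ts_ta, site)
  daily <- data.frame(
    squirrel_date = sqd,
    day_of_year = as.integer(strftime(as.POSIXct(paste(sqd + 1, "12:00"),
                                                 tz = site$tz), "%j")),
    rest_level = rhythm$mode_rest + level_offset +
      rhythm$trend_per_day *
        (as.integer(strftime(as.POSIXct(paste(sqd + 1, "12:00"),
                                        tz = site$tz), "%j")) - doy0) +
      rhythm$ambient_coupling * lev_of(sqd + 1),
    active_level = rhythm$mode_active + level_offset,
    ta_max = vapply(sqd, function(d)
      if (any(ta_sq_date == d)) max(ta[ta_sq_date == d]) else NA_real_,
      numeric(1)),
    torpor = sqd %in% torpid_days)

  list(tb = data.frame(timestamp = ts_tb, temperature = tb),
       ta = data.frame(timestamp = ts_ta, temperature = ta),
       truth = list(daily = daily, torpor = torpor_tbl,
                    events = ev, mode_rest = rhythm$mode_rest,
                    mode_active = rhythm$mode_active,
                    individual = individual, seed = as.integer(seed)))
}

# maximal runs of TRUE as (start, end) index pairs (inclusive)
run_spans <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
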