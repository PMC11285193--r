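# Rolling mean / sd over contiguous windows via cumulative sums (O(n)).
roll_mean <- function(x, w) {
  cs <- c(0, cumsum(x))
  (cs[(w + 1):(length(x) + 1)] - cs[1:(length(x) - w + 1)]) / w
}

roll_sd <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  s1 <- cs[(w + 1):(length(x) + 1)] - cs[1:(length(x) - w + 1)]
  s2 <- cs2[(w + 1):(length(x) + 1)] - cs2[1:(length(x) - w + 1)]
  v <- pmax(0, (s2 - s1 * s1 / w) / (w - 1))
  sqrt(v)
}

#' Select the lowest, most stable resting window in a CO2 stretch
#'
#' Within one measurement stretch, finds the contiguous `n_low`-sample window
#' with the lowest mean CO2 signal and, inside it, the contiguous
#' `n_stable`-sample sub-window with the smallest standard deviation. Ties
#' are broken by the earliest start. At the default 2 Hz sampling this is the
#' "lowest 1,200 values (10 min), then the 600 most stable (5 min)" rule.
#'
#' @param co2 Numeric vector, the CO2 signal over one stretch (uniform
#'   sampling).
#' @param n_low Size of the lowest-mean window, samples. Default 1200.
#' @param n_stable Size of the stable sub-window, samples. Default 600.
#' @return `NULL` if the stretch is shorter than `n_low` (with a message);
#'   otherwise a list with `start` (1-based index of the selected sub-window),
#'   `end` (exclusive), `low_start` (start of the 10-min window), `co2_mean`
#'   and `co2_sd` over the selected sub-window.
#' @examples
#' w <- select_resting_window(rep(1, 2400), n_low = 1200, n_stable = 600)
#' w$start # 1 (earliest tie)
#' @export
select_resting_window <- function(co2, n_low = 1200, n_stable = 600) {
  stopifnot(n_stable <= n_low)
  if (length(co2) < n_low) {
    message("stretch of ", length(co2), " samples shorter than n_low = ",
            n_low, "; skipped")
    return(NULL)
  }
  i_low <- which.min(roll_mean(co2, n_low))
  sub <- co2[i_low:(i_low + n_low - 1)]
  s <- roll_sd(sub, n_stable)
  j <- which.min(s)
  start <- i_low + j - 1L
  win <- co2[start:(start + n_stable - 1)]
  list(start = start, end = start + n_stable,
       low_start = i_low, co2_mean = mean(win), co2_sd = s[j])
}

#' Tile a trial into stretches and collect candidate resting windows
#'
#' Tiles non-overlapping stretches of `stretch_min` minutes forward from each
#' temperature step's start (any remainder shorter than a full stretch is
#' dropped) and applies [select_resting_window()] to the excurrent CO2 signal
#' of each stretch. Several candidates per step are possible.
#'
#' @param trace A [respirometry_trace()].
#' @param steps Data frame of temperature steps with columns `step`,
#'   `ta_set`, `start_s`, `end_s` (see [steps_from_events()]).
#' @param stretch_min Stretch length, minutes. Default 40.
#' @param n_low,n_stable Window sizes in samples (see
#'   [select_resting_window()]).
#' @return Data frame of candidate windows: step, ta_set, stretch index,
#'   window start/end in seconds (half-open) and in sample indices, CO2 mean
#'   and SD. Zero rows if no step contains a complete stretch.
#' @export
segment_trial <- function(trace, steps, stretch_min = 40,
                          n_low = 1200, n_stable = 600) {
  hz <- attr(trace, "hz")
  if (is.null(hz)) hz <- 2
  w <- round(stretch_min * 60 * hz)
  out <- list()
  for (i in seq_len(nrow(steps))) {
    i0 <- which(trace$time >= steps$start_s[i] & trace$time < steps$end_s[i])
    n_str <- length(i0) %/% w
    if (n_str == 0) {
      message("step ", steps$step[i], " (", steps$ta_set[i],
              " degC): no complete ", stretch_min, "-min stretch")
      next
    }
    for (s in seq_len(n_str)) {
      idx <- i0[((s - 1) * w + 1):(s * w)]
      win <- select_resting_window(trace$fe_co2[idx], n_low, n_stable)
      if (is.null(win)) next
      g0 <- idx[win$start]                 # global sample index
      out[[length(out) + 1]] <- data.frame(
        step = steps$step[i], ta_set = steps$ta_set[i], stretch = s,
        start_s = trace$time[g0],
        end_s = trace$time[g0] + n_stable / hz,
        i_start = g0, i_end = g0 + n_stable,
        co2_mean = win$co2_mean, co2_sd = win$co2_sd)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(step = integer(0), ta_set = numeric(0), stretch = integer(0),
                  start_s = numeric(0), end_s = numeric(0),
                  i_start = integer(0), i_end = integer(0),
                  co2_mean = numeric(0), co2_sd = numeric(0))
}

#' Activity threshold from labelled active intervals
#'
#' The CO2-variability threshold above which a candidate window is considered
#' active. With labelled active intervals the threshold is the minimum (or
#' mean, by configuration) of the per-interval CO2 standard deviations; with
#' no labels it falls back to a quantile of all rolling 5-min SDs.
#'
#' @param trace A [respirometry_trace()].
#' @param active_intervals Data frame with `start_s`, `end_s` of observed
#'   activity (may have zero rows).
#' @param rule `"min"` (default) or `"mean"` across intervals.
#' @param fallback_q Quantile used when no interval is labelled. Default 0.9.
#' @param window Rolling window for the fallback, samples. Default 600.
#' @return The threshold tau, in CO2 fraction units.
#' @export
activity_threshold <- function(trace, active_intervals,
                               rule = c("min", "mean"),
                               fallback_q = 0.90, window = 600) {
  rule <- match.arg(rule)
  if (!is.null(active_intervals) && nrow(active_intervals) > 0) {
    sds <- vapply(seq_len(nrow(active_intervals)), function(b) {
      idx <- trace$time >= active_intervals$start_s[b] &
        trace$time < active_intervals$end_s[b]
      if (sum(idx) < 2) return(NA_real_)
      stats::sd(trace$fe_co2[idx])
    }, numeric(1))
    sds <- sds[!is.na(sds)]
    if (length(sds))
      return(if (rule == "min") min(sds) else mean(sds))
  }
  message("no labelled active intervals; falling back to the ",
          fallback_q, " quantile of rolling CO2 SDs")
  as.numeric(stats::quantile(roll_sd(trace$fe_co2, window), fallback_q))
}

#' Apply the exclusion tests to candidate resting windows
#'
#' Flags each candidate that (a) overlaps the settle-in period at trial
#' start, (b) overlaps the exclusion radius around a disruption event,
#' (c) has CO2 SD at or above the activity threshold `tau`, or (d) overlaps a
#' visually labelled active interval. Among the retained candidates of each
#' temperature step, the one with the lowest mean CO2 is marked the step's
#' best estimate.
#'
#' @param candidates Output of [segment_trial()].
#' @param events Data frame of trial events (`time`, `kind`, `note`) or NULL.
#' @param tau Activity threshold from [activity_threshold()].
#' @param settle_in_s Settle-in duration, s. Default 3600.
#' @param disruption_radius_s Exclusion radius around disruptions, s.
#'   Default 3600.
#' @param visual_intervals Optional data frame (`start_s`, `end_s`) of
#'   visually confirmed activity.
#' @param visual_pad_s Seconds appended after each visual interval before the
#'   overlap test, to cover the chamber-washout tail of a burst (washout is
#'   causal, so no padding is applied before the interval). Default 0 (raw
#'   overlap rule); [extract_rmr()] passes the configured `activity_pad_s`.
#' @return The candidates with logical columns `settle_in`, `disruption`,
#'   `activity`, `visual`, `retained`, `best`.
#' @export
apply_exclusion_tests <- function(candidates, events = NULL, tau = Inf,
                                  settle_in_s = 3600,
                                  disruption_radius_s = 3600,
                                  visual_intervals = NULL,
                                  visual_pad_s = 0) {
  n <- nrow(candidates)
  overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1  # half-open
  settle <- overlaps(candidates$start_s, candidates$end_s, 0, settle_in_s)
  disr <- rep(FALSE, n)
  if (!is.null(events) && nrow(events)) {
    dts <- events$time[events$kind == "disruption"]
    for (d in dts)
      disr <- disr | overlaps(candidates$start_s, candidates$end_s,
                              d - disruption_radius_s,
                              d + disruption_radius_s)
  }
  act <- candidates$co2_sd >= tau
  vis <- rep(FALSE, n)
  if (!is.null(visual_intervals) && nrow(visual_intervals)) {
    for (b in seq_len(nrow(visual_intervals)))
      vis <- vis | overlaps(candidates$start_s, candidates$end_s,
                            visual_intervals$start_s[b],
                            visual_intervals$end_s[b] + visual_pad_s)
  }
  candidates$settle_in <- settle
  candidates$disruption <- disr
  candidates$activity <- act
  candidates$visual <- vis
  candidates$retained <- !(settle | disr | act | vis)
  candidates$best <- FALSE
  for (st in unique(candidates$step)) {
    ret <- which(candidates$step == st & candidates$retained)
    if (length(ret)) {
      candidates$best[ret[which.min(candidates$co2_mean[ret])]] <- TRUE
    } else if (any(candidates$step == st)) {
      message("step ", st, ": all candidates excluded (",
              paste(unique(c("settle_in", "disruption", "activity",
                             "visual")[c(any(settle[candidates$step == st]),
                                         any(disr[candidates$step == st]),
                                         any(act[candidates$step == st]),
                                         any(vis[candidates$step == st]))]),
                    collapse = ", "), ")")
    }
  }
  candidates
}

#' Extract resting metabolic bouts from a trial
#'
#' Full extraction: tile stretches, select candidate windows, derive the
#' activity threshold, apply the exclusion tests, and summarise gas-exchange
#' rates and energetics over each window.
#'
#' @param trace A [respirometry_trace()].
#' @param steps Temperature-step table (`step`, `ta_set`, `start_s`,
#'   `end_s`).
#' @param events Optional events data frame.
#' @param active_intervals Optional labelled activity (`start_s`, `end_s`)
#'   used both for the threshold and as visual exclusions.
#' @param config A [run_config()].
#' @param mass_g Body mass; defaults to the trace attribute.
#' @param trial_id,squirrel_id Identifiers carried into the bout table.
#' @return Data frame of resting bouts, one row per candidate window, with
#'   per-window mean rates (`vo2`, `vco2`, `vh2o`, `rq`, `mhp`, `ehl`,
#'   `ehl_mhp`), `ta_measured`, `t_sub`, exclusion flags, `retained` and
#'   `best`.
#' @examples
#' sim <- generate_respirometry_trial(physiology_params(),
#'   cbind(c(25, 32), c(120, 60)), seed = 3)
#' bouts <- extract_rmr(sim$trace, sim$truth$steps,
#'   active_intervals = sim$truth$activity)
#' subset(bouts, best, c(ta_set, vo2))
#' @export
extract_rmr <- function(trace, steps, events = NULL, active_intervals = NULL,
                        config = run_config(), mass_g = NULL,
                        trial_id = "trial1", squirrel_id = "sq1") {
  if (is.null(mass_g)) mass_g <- attr(trace, "mass_g")
  if (is.null(mass_g)) mass_g <- NA_real_
  cand <- segment_trial(trace, steps, stretch_min = config$stretch_min,
                        n_low = config$n_low, n_stable = config$n_stable)
  if (!nrow(cand)) return(cbind(trial = character(0), cand))
  tau <- activity_threshold(trace, active_intervals,
                            rule = config$activity_sd_rule,
                            fallback_q = config$activity_fallback_q,
                            window = config$n_stable)
  cand <- apply_exclusion_tests(cand, events, tau,
                                settle_in_s = config$settle_in_s,
                                disruption_radius_s =
                                  config$disruption_radius_s,
                                visual_intervals = active_intervals,
                                visual_pad_s = config$activity_pad_s)
  rates <- rates_from_fractions(trace)
  agg <- function(x, i0, i1) mean(x[i0:(i1 - 1)])
  k <- nrow(cand)
  vo2 <- vco2 <- vh2o <- ta <- tsb <- numeric(k)
  for (i in seq_len(k)) {
    vo2[i] <- agg(rates$vo2, cand$i_start[i], cand$i_end[i])
    vco2[i] <- agg(rates$vco2, cand$i_start[i], cand$i_end[i])
    vh2o[i] <- agg(rates$vh2o, cand$i_start[i], cand$i_end[i])
    ta[i] <- agg(trace$t_chamber, cand$i_start[i], cand$i_end[i])
    tsb[i] <- agg(trace$t_sub, cand$i_start[i], cand$i_end[i])
  }
  en <- energetics(data.frame(vo2 = vo2, vco2 = vco2, vh2o = vh2o))
  out <- data.frame(trial = trial_id, squirrel = squirrel_id,
                    mass_g = mass_g, cand[, c("step", "ta_set")],
                    ta_measured = ta, t_sub = tsb, en,
                    cand[, c("start_s", "end_s", "co2_mean", "co2_sd",
                             "settle_in", "disruption", "activity", "visual",
                             "retained", "best")])
  rownames(out) <- NULL
  out
}

#' Temperature steps from an events table
#'
#' Builds the step table used by [segment_trial()] from `temperature_step`
#' events whose `note` holds the set temperature.
#'
#' @param events Data frame with `time`, `kind`, `note`.
#' @param trial_end_s End of the trial, seconds.
#' @return Data frame `step`, `ta_set`, `start_s`, `end_s`.
#' @export
steps_from_events <- function(events, trial_end_s) {
  ev <- events[events$kind == "temperature_step", , drop = FALSE]
  if (!nrow(ev)) stop("no temperature_step events found", call. = FALSE)
  ev <- ev[order(ev$time), ]
  ta <- suppressWarnings(as.numeric(ev$note))
  if (any(is.na(ta)))
    stop("temperature_step note must hold the set temperature",
         call. = FALSE)
  data.frame(step = seq_len(nrow(ev)), ta_set = ta, start_s = ev$time,
             end_s = c(ev$time[-1], trial_end_s))
}
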