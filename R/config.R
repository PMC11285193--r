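#' Run configuration
#'
#' A single flat configuration object carried through the pipeline. Every key
#' has a documented default; the configuration (and its hash) is embedded in
#' all written outputs so a run can be reproduced exactly.
#'
#' @param site_lat,site_lon,site_tz Study site (see [site()]).
#' @param trace_hz Respirometry trace sampling rate, Hz. Default 2 (the
#'   resting-window arithmetic of 1200 samples = 10 min assumes 2 Hz).
#' @param tb_minutes Body-temperature logger sampling interval, minutes.
#'   Default 5.
#' @param ta_minutes Ambient logger sampling interval, minutes. Default 45.
#' @param n_low Number of samples in the lowest-mean CO2 window. Default 1200.
#' @param n_stable Number of samples in the most-stable sub-window.
#'   Default 600.
#' @param stretch_min Length of the measurement stretches tiled within each
#'   temperature step, minutes. Default 40.
#' @param settle_in_s Seconds excluded at trial start while the animal
#'   settles. Default 3600.
#' @param disruption_radius_s Seconds excluded either side of a disruption
#'   event. Default 3600.
#' @param activity_sd_rule How the activity threshold is derived from
#'   labelled active intervals: `"min"` (default) or `"mean"` of their CO2
#'   standard deviations.
#' @param activity_fallback_q Quantile of rolling CO2 SDs used when no active
#'   interval is labelled. Default 0.90.
#' @param activity_pad_s Seconds added after each visually labelled active
#'   interval when excluding candidate windows: CO2 released
#'   during a burst of activity persists in the chamber and decays with the
#'   washout time constant, so windows immediately after a burst still carry
#'   its signal. Default 1200 (about four time constants of a typical small
#'   chamber, >98% washed out).
#' @param torpor_threshold Body temperature below which a sample counts as
#'   torpid, degC. Default 35.
#' @param torpor_min_duration Minimum duration of a torpor bout, minutes.
#'   Default 30.
#' @param mode_bin Bin width used for modal temperatures, degC. Default 0.1.
#' @param psi_lower,psi_upper Breakpoint search bounds, degC (NA: data range).
#' @param grid_step Grid-search step for the breakpoint fallback, degC.
#'   Default 0.05.
#' @param n_boot Bootstrap replicates for the bootstrap CI. Default 999.
#' @param seed Integer RNG seed recorded in every output. Default 1.
#' @return A `run_config` object (flat named list).
#' @examples
#' cfg <- run_config(seed = 42)
#' config_hash(cfg)
#' @export
run_config <- function(site_lat = 44.935, site_lon = -68.682,
                       site_tz = "America/New_York",
                       trace_hz = 2, tb_minutes = 5, ta_minutes = 45,
                       n_low = 1200, n_stable = 600, stretch_min = 40,
                       settle_in_s = 3600, disruption_radius_s = 3600,
                       activity_sd_rule = c("min", "mean"),
                       activity_fallback_q = 0.90, activity_pad_s = 1200,
                       torpor_threshold = 35, torpor_min_duration = 30,
                       mode_bin = 0.1,
                       psi_lower = NA_real_, psi_upper = NA_real_,
                       grid_step = 0.05, n_boot = 999, seed = 1L) {
  activity_sd_rule <- match.arg(activity_sd_rule)
  cfg <- list(site_lat = site_lat, site_lon = site_lon, site_tz = site_tz,
              trace_hz = trace_hz, tb_minutes = tb_minutes,
              ta_minutes = ta_minutes,
              n_low = n_low, n_stable = n_stable, stretch_min = stretch_min,
              settle_in_s = settle_in_s,
              disruption_radius_s = disruption_radius_s,
              activity_sd_rule = activity_sd_rule,
              activity_fallback_q = activity_fallback_q,
              activity_pad_s = activity_pad_s,
              torpor_threshold = torpor_threshold,
              torpor_min_duration = torpor_min_duration,
              mode_bin = mode_bin,
              psi_lower = psi_lower, psi_upper = psi_upper,
              grid_step = grid_step, n_boot = n_boot,
              seed = as.integer(seed))
  durs <- c("trace_hz", "tb_minutes", "ta_minutes", "n_low", "n_stable",
            "stretch_min", "settle_in_s", "disruption_radius_s",
            "torpor_min_duration", "mode_bin", "grid_step", "n_boot")
  for (k in durs)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config key '", k, "' must be > 0", call. = FALSE)
  if (cfg$n_stable > cfg$n_low)
    stop("n_stable must not exceed n_low", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Hash a configuration (or any serialisable object)
#'
#' MD5 of a canonical text serialisation; used to stamp outputs so that runs
#' with identical configuration are recognisably identical.
#'
#' @param x Object to hash (typically a [run_config()]).
#' @return Lowercase 32-character MD5 string.
#' @export
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # deparse gives a stable text form independent of in-memory representation
  writeLines(deparse(unclass(x), control = c("exact")), f)
  unname(tools::md5sum(f))
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (", config_hash(x), ")\n", sep = "")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Derive a per-stage child seed from the global seed; stays below 2^31.
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stage)
}
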