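#' Physiological parameters for the respirometry forward model
#'
#' Bundles the Scholander–Irving parameters used by
#' [generate_respirometry_trial()]: a flat resting metabolic rate within the
#' thermoneutral zone, a linear rise below the lower critical temperature
#' (LCT), evaporative water loss (EWL) inflecting upward above its own
#' breakpoint, and subcutaneous temperature rising above a third breakpoint.
#' Defaults describe a ~60 g nocturnal sciurid: LCT 29.8 degC, EWL breakpoint
#' 36.2 degC, subcutaneous breakpoint 33.64 degC.
#'
#' @param bmr Resting metabolic rate within the thermoneutral zone,
#'   ml O2 h^-1 (whole animal). Default 90.
#' @param lct Lower critical temperature, degC. Default 29.8.
#' @param slope_below_lct Slope of VO2 against ambient temperature below the
#'   LCT, ml O2 h^-1 degC^-1; must be negative. Default -9.
#' @param ewl_base Evaporative water loss within/below the thermoneutral
#'   zone, mg H2O h^-1. Default 55.
#' @param psi_ewl Ambient temperature at which EWL inflects upward, degC.
#'   Default 36.2.
#' @param ewl_slope_above Slope of EWL above `psi_ewl`, mg h^-1 degC^-1.
#'   Default 45.
#' @param tsub_base Subcutaneous temperature at or below its breakpoint,
#'   degC. Default 36.5.
#' @param psi_tsub Ambient temperature at which subcutaneous temperature
#'   starts tracking ambient, degC. Default 33.64.
#' @param tsub_slope_above Slope of subcutaneous temperature above
#'   `psi_tsub`, degC per degC. Default 0.55.
#' @param rq Respiratory quotient VCO2/VO2, in [0.7, 1.0]. Default 0.85.
#' @param mass_g Body mass, grams. Default 60.6.
#' @return An object of class `physiology_params` (a validated list).
#' @examples
#' p <- physiology_params()
#' p$lct
#' @export
physiology_params <- function(bmr = 90, lct = 29.8, slope_below_lct = -9,
                              ewl_base = 55, psi_ewl = 36.2,
                              ewl_slope_above = 45,
                              tsub_base = 36.5, psi_tsub = 33.64,
                              tsub_slope_above = 0.55,
                              rq = 0.85, mass_g = 60.6) {
  p <- list(bmr = bmr, lct = lct, slope_below_lct = slope_below_lct,
            ewl_base = ewl_base, psi_ewl = psi_ewl,
            ewl_slope_above = ewl_slope_above,
            tsub_base = tsub_base, psi_tsub = psi_tsub,
            tsub_slope_above = tsub_slope_above,
            rq = rq, mass_g = mass_g)
  stopifnot(p$bmr > 0, p$ewl_base > 0, p$mass_g > 0)
  if (p$rq < 0.7 || p$rq > 1.0)
    stop("rq must lie in [0.7, 1.0]", call. = FALSE)
  if (p$slope_below_lct >= 0)
    stop("slope_below_lct must be negative (VO2 rises as Ta falls)",
         call. = FALSE)
  class(p) <- "physiology_params"
  p
}

#' Circadian rhythm parameters for the free-ranging generator
#'
#' Parameters of the simulated core body-temperature rhythm used by
#' [generate_free_ranging()]. The animal is nocturnal: the active plateau
#' (`mode_active`) spans the night, the rest plateau (`mode_rest`) the day,
#' with cosine transition ramps centred on sunrise and sunset. Realistic
#' structure beyond the plateaus: a brief post-dusk overshoot and pre-dawn
#' bump during activity, a late-rest dip before dusk, an AR(1) noise term,
#' day-level coupling of the rest plateau to daily maximum ambient
#' temperature, a slow day-of-year trend, and rare shallow torpor bouts.
#'
#' @param mode_rest Rest-phase (daytime) modal body temperature, degC.
#'   Default 37.5.
#' @param mode_active Active-phase (night) modal body temperature, degC.
#'   Default 39.9.
#' @param transition_minutes Width of the dawn/dusk ramp, minutes. Default 60.
#' @param noise_sd Stationary standard deviation of the AR(1) noise, degC.
#'   Default 0.3.
#' @param ar_coeff AR(1) coefficient at the 5-min sampling step, in [0, 1).
#'   Default 0.7.
#' @param ambient_coupling Shift in rest-phase level per degC of daily
#'   maximum ambient temperature above the reference (22 degC), degC/degC.
#'   Default 0.04.
#' @param trend_per_day Linear drift of the whole rhythm with day of year,
#'   degC per day (negative: warmer earlier in summer). Default -0.0022.
#' @param torpor_prob_per_day Probability that a given squirrel-day contains
#'   a shallow torpor bout. Default 0.0025.
#' @param torpor_depth Minimum body temperature reached during a torpor
#'   bout, degC. Default 34.6.
#' @param torpor_duration_min Duration of a torpor bout, minutes. Default 120.
#' @param bump_dusk Post-dusk activity overshoot above the active plateau,
#'   degC. Default 0.5.
#' @param bump_dawn Pre-dawn activity bump above the active plateau, degC.
#'   Default 0.3.
#' @param rest_dip Depth of the late-rest dip below the rest plateau, degC.
#'   Default 0.8.
#' @return An object of class `rhythm_params`.
#' @examples
#' rhythm_params(noise_sd = 0)$mode_active
#' @export
rhythm_params <- function(mode_rest = 37.5, mode_active = 39.9,
                          transition_minutes = 60,
                          noise_sd = 0.3, ar_coeff = 0.7,
                          ambient_coupling = 0.04,
                          trend_per_day = -0.0022,
                          torpor_prob_per_day = 0.0025,
                          torpor_depth = 34.6,
                          torpor_duration_min = 120,
                          bump_dusk = 0.5, bump_dawn = 0.3,
                          rest_dip = 0.8) {
  p <- list(mode_rest = mode_rest, mode_active = mode_active,
            transition_minutes = transition_minutes,
            noise_sd = noise_sd, ar_coeff = ar_coeff,
            ambient_coupling = ambient_coupling,
            trend_per_day = trend_per_day,
            torpor_prob_per_day = torpor_prob_per_day,
            torpor_depth = torpor_depth,
            torpor_duration_min = torpor_duration_min,
            bump_dusk = bump_dusk, bump_dawn = bump_dawn,
            rest_dip = rest_dip)
  if (p$mode_active <= p$mode_rest)
    stop("mode_active must exceed mode_rest", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$ar_coeff < 0 || p$ar_coeff >= 1)
    stop("ar_coeff must lie in [0, 1)", call. = FALSE)
  stopifnot(p$transition_minutes > 0, p$torpor_duration_min > 0)
  class(p) <- "rhythm_params"
  p
}

#' Study site description
#'
#' @param lat Latitude, decimal degrees (positive north).
#' @param lon Longitude, decimal degrees (positive east).
#' @param tz Olson timezone name.
#' @return A `site` object. Defaults describe a mixed forest site in
#'   central Maine, USA, in the eastern time zone.
#' @examples
#' site()
#' @export
site <- function(lat = 44.935, lon = -68.682, tz = "America/New_York") {
  if (abs(lat) >= 66.5)
    stop("polar latitudes (|lat| >= 66.5) are not supported", call. = FALSE)
  if (abs(lon) > 180) stop("lon out of range", call. = FALSE)
  if (!tz %in% OlsonNames()) stop("unknown timezone: ", tz, call. = FALSE)
  structure(list(lat = lat, lon = lon, tz = tz), class = "site")
}
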