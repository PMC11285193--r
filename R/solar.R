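# NOAA solar position algorithm (Meeus-based, as in the NOAA solar
# calculator). Accuracy of sunrise/sunset is well under a minute at
# temperate latitudes, ample for day/night phase assignment.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Core NOAA equations evaluated at julian centuries jc; returns solar
# declination (radians) and equation of time (minutes).
noaa_sun <- function(jc) {
  l0 <- (280.46646 + jc * (36000.76983 + jc * 0.0003032)) %% 360
  m <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  c <- sin(deg2rad(m)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(deg2rad(2 * m)) * (0.019993 - 0.000101 * jc) +
    sin(deg2rad(3 * m)) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * jc
  lambda <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(deg2rad(omega))
  decl <- asin(sin(deg2rad(eps)) * sin(deg2rad(lambda)))
  y <- tan(deg2rad(eps / 2))^2
  eqtime <- 4 * rad2deg(
    y * sin(2 * deg2rad(l0)) - 2 * e * sin(deg2rad(m)) +
      4 * e * y * sin(deg2rad(m)) * cos(2 * deg2rad(l0)) -
      0.5 * y^2 * sin(4 * deg2rad(l0)) -
      1.25 * e^2 * sin(2 * deg2rad(m)))
  list(decl = decl, eqtime = eqtime)
}

#' Sunrise and sunset times for calendar dates at a site
#'
#' NOAA solar position algorithm with the standard -0.833 degree horizon
#' (refraction + solar radius). Polar conditions (no sunrise/sunset on the
#' date) raise an error; the supported study region is non-polar.
#'
#' @param dates `Date` vector (interpreted as local calendar dates at the
#'   site).
#' @param site A [site()] object.
#' @return Data frame with `date`, `sunrise`, `sunset` (POSIXct in the site
#'   timezone).
#' @examples
#' solar_events(as.Date("2018-07-01"), site())
#' @export
solar_events <- function(dates, site) {
  stopifnot(inherits(site, "site"))
  dates <- as.Date(dates)
  jd <- as.numeric(dates) + 2440587.5          # JD at 00:00 UTC
  jc <- (jd + 0.5 - site$lon / 360 - 2451545) / 36525  # near local solar noon
  s <- noaa_sun(jc)
  lat <- deg2rad(site$lat)
  cos_ha <- cos(deg2rad(90.833)) / (cos(lat) * cos(s$decl)) -
    tan(lat) * tan(s$decl)
  if (any(abs(cos_ha) > 1))
    stop("unsupported input: no sunrise/sunset on this date at this latitude",
         call. = FALSE)
  ha <- rad2deg(acos(cos_ha))                   # degrees
  noon_utc <- 720 - 4 * site$lon - s$eqtime     # minutes after 00:00 UTC
  rise_utc <- noon_utc - 4 * ha
  set_utc <- noon_utc + 4 * ha
  midnight_utc <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  sunrise <- midnight_utc + rise_utc * 60
  sunset <- midnight_utc + set_utc * 60
  attr(sunrise, "tzone") <- site$tz
  attr(sunset, "tzone") <- site$tz
  data.frame(date = dates, sunrise = sunrise, sunset = sunset)
}

#' Day/night phase of timestamps
#'
#' Categorises each timestamp as `day` or `night` by the sunrise and sunset
#' of its local calendar date at the site; day is the half-open interval
#' [sunrise, sunset).
#'
#' @param timestamps POSIXct vector (timezone-aware).
#' @param site A [site()] object.
#' @return Data frame with `phase` (factor day/night), `sunrise`, `sunset`.
#' @export
solar_phase <- function(timestamps, site) {
  loc <- as.POSIXlt(timestamps, tz = site$tz)
  dates <- as.Date(loc)
  ud <- sort(unique(dates))
  ev <- solar_events(ud, site)
  i <- match(dates, ev$date)
  phase <- ifelse(timestamps >= ev$sunrise[i] & timestamps < ev$sunset[i],
                  "day", "night")
  data.frame(phase = factor(phase, levels = c("day", "night")),
             sunrise = ev$sunrise[i], sunset = ev$sunset[i])
}

#' Dusk-to-dusk ("squirrel-defined") dates
#'
#' Assigns each timestamp the date `D` such that the timestamp falls in
#' `[sunset(D), sunset(D+1))`, so that a nocturnal activity period is not
#' split across two calendar dates.
#'
#' @inheritParams solar_phase
#' @return `Date` vector of squirrel-defined dates.
#' @examples
#' ts <- as.POSIXct("2018-07-02 03:00", tz = "America/New_York")
#' assign_squirrel_date(ts, site()) # "2018-07-01"
#' @export
assign_squirrel_date <- function(timestamps, site) {
  loc <- as.POSIXlt(timestamps, tz = site$tz)
  dates <- as.Date(loc)
  ud <- sort(unique(dates))
  ev <- solar_events(ud, site)
  i <- match(dates, ev$date)
  ifelse_date <- dates
  after_dusk <- timestamps >= ev$sunset[i]
  ifelse_date[!after_dusk] <- dates[!after_dusk] - 1
  ifelse_date
}
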