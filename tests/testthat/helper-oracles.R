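# Independent oracles used by the tests. These deliberately avoid the code
# paths of the implementation they check.

# Exhaustive resting-window search: all contiguous n_low-sample window means
# via a moving-average filter, then every contiguous n_stable sub-window SD
# via sd(). Returns the selected sub-window start (1-based).
brute_force_window <- function(co2, n_low, n_stable) {
  n <- length(co2)
  if (n < n_low) return(NULL)
  means <- stats::filter(co2, rep(1 / n_low, n_low), sides = 1)
  means <- means[n_low:n]                      # mean ending at i -> start
  i_low <- which.min(means)
  sub <- co2[i_low:(i_low + n_low - 1)]
  sds <- vapply(1:(n_low - n_stable + 1), function(j)
    stats::sd(sub[j:(j + n_stable - 1)]), numeric(1))
  j <- which.min(sds)
  i_low + j - 1L
}

# Low-precision solar ephemeris (Astronomical Almanac 1990 formulation),
# coded independently of the NOAA implementation in R/solar.R.
almanac_sun_events <- function(date, lat, lon, tz) {
  jd <- as.numeric(as.Date(date)) + 2440587.5
  nd <- jd + 0.5 - lon / 360 - 2451545
  L <- (280.460 + 0.9856474 * nd) %% 360
  g <- (357.528 + 0.9856003 * nd) %% 360
  gr <- g * pi / 180
  lam <- (L + 1.915 * sin(gr) + 0.020 * sin(2 * gr)) %% 360
  eps <- 23.439 - 0.0000004 * nd
  lamr <- lam * pi / 180; epsr <- eps * pi / 180
  decl <- asin(sin(epsr) * sin(lamr))
  alpha <- atan2(cos(epsr) * sin(lamr), cos(lamr)) * 180 / pi
  eot <- 4 * ((L - alpha + 180) %% 360 - 180)   # minutes
  latr <- lat * pi / 180
  cos_ha <- (cos(90.833 * pi / 180) - sin(latr) * sin(decl)) /
    (cos(latr) * cos(decl))
  if (abs(cos_ha) > 1) return(NULL)
  ha <- acos(cos_ha) * 180 / pi
  noon_utc <- 720 - 4 * lon - eot
  mid <- as.POSIXct(paste(as.Date(date), "00:00:00"), tz = "UTC")
  list(sunrise = mid + (noon_utc - 4 * ha) * 60,
       sunset = mid + (noon_utc + 4 * ha) * 60)
}

# Closed-form Heterothermy Index.
hi_oracle <- function(x, m) sqrt(sum((m - x)^2) / (length(x) - 1))

# Hand mass-balance for a single steady state (used against
# rates_from_fractions): given true per-minute rates, build fractions.
fractions_from_rates <- function(flow, fi_o2, fi_co2, fi_h2o,
                                 vo2_m, vco2_m, vh2o_ml_m) {
  outflow <- flow - vo2_m + vco2_m + vh2o_ml_m
  data.frame(fe_o2 = (flow * fi_o2 - vo2_m) / outflow,
             fe_co2 = (flow * fi_co2 + vco2_m) / outflow,
             fe_h2o = (flow * fi_h2o + vh2o_ml_m) / outflow,
             fi_o2 = fi_o2, fi_co2 = fi_co2, fi_h2o = fi_h2o,
             flow = flow)
}

# Small standard trial schedule used across tests.
test_schedule <- function() cbind(c(25, 30, 34, 38), c(120, 60, 60, 60))
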