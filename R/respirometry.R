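#' Gas-exchange rates from analyzer fractions
#'
#' Converts excurrent/incurrent fractions and incurrent flow to oxygen
#' consumption, carbon dioxide production and water loss using the
#' nitrogen-balance (dilution-exact) equations. Nitrogen is inert, so the
#' excurrent flow is `flow * FiN2 / FeN2` with
#' `FN2 = 1 - FO2 - FCO2 - FH2O`; the species rates follow by mass balance.
#' This form is exact when O2, CO2 and water vapour are measured
#' simultaneously on unscrubbed air, which makes it the exact inverse of the
#' synthetic generator's forward model.
#'
#' @param trace A [respirometry_trace()] or any data frame with the fraction
#'   and flow columns.
#' @return Data frame, one row per sample: `vo2` (ml O2 h^-1), `vco2`
#'   (ml CO2 h^-1), `vh2o` (mg H2O h^-1) and a logical `flagged` column
#'   marking samples whose VO2 is negative beyond noise tolerance.
#' @examples
#' sim <- generate_respirometry_trial(physiology_params(),
#'   cbind(25, 30), seed = 1, noise_sd = 0, activity = FALSE,
#'   washout_tau = 0)
#' r <- rates_from_fractions(sim$trace)
#' all.equal(r$vo2, sim$truth$rates$vo2, tolerance = 1e-9)
#' @export
rates_from_fractions <- function(trace) {
  fe_n2 <- 1 - trace$fe_o2 - trace$fe_co2 - trace$fe_h2o
  fi_n2 <- 1 - trace$fi_o2 - trace$fi_co2 - trace$fi_h2o
  if (any(fe_n2 <= 0))
    stop("integrity error: excurrent nitrogen fraction <= 0", call. = FALSE)
  outflow <- trace$flow * fi_n2 / fe_n2
  vo2_m <- trace$flow * trace$fi_o2 - outflow * trace$fe_o2
  vco2_m <- outflow * trace$fe_co2 - trace$flow * trace$fi_co2
  vh2o_m <- outflow * trace$fe_h2o - trace$flow * trace$fi_h2o
  # negative VO2 beyond what analyzer noise can explain
  tol <- if (length(vo2_m) >= 3)
    6 * stats::mad(diff(vo2_m)) / sqrt(2) + 1e-12 else 1e-9
  data.frame(vo2 = vo2_m * 60,
             vco2 = vco2_m * 60,
             vh2o = vh2o_m * 60 * MG_PER_ML_H2O,
             flagged = vo2_m < -tol)
}

# J per ml O2 as a function of RQ (oxyjoule conversion) and latent heat of
# vaporisation in J per mg of water; overridable via arguments below.
OXYJOULE_A <- 16
OXYJOULE_B <- 5.164
LATENT_J_PER_MG <- 2.41

#' Derived energetics: RQ, heat production, evaporative heat loss
#'
#' Completes a set of gas-exchange rates with the respiratory quotient
#' (RQ = VCO2/VO2), metabolic heat production
#' `MHP = VO2 * (16 + 5.164 * RQ)` J h^-1 (oxyjoule conversion), evaporative
#' heat loss `EHL = 2.41 * VH2O` J h^-1 (latent heat 2.41 J mg^-1), and their
#' ratio EHL/MHP.
#'
#' @param rates Data frame with columns `vo2` (ml h^-1), `vco2` (ml h^-1),
#'   `vh2o` (mg h^-1); `vo2` must be positive.
#' @param oxyjoule Length-2 numeric (a, b): J per ml O2 = a + b * RQ.
#' @param latent_heat J per mg of water evaporated.
#' @return The input with columns `rq`, `mhp`, `ehl`, `ehl_mhp` added and a
#'   logical `rq_suspect` flag for RQ outside [0.6, 1.1].
#' @examples
#' energetics(data.frame(vo2 = 1000, vco2 = 1000, vh2o = 0))$mhp # 21164
#' @export
energetics <- function(rates, oxyjoule = c(OXYJOULE_A, OXYJOULE_B),
                       latent_heat = LATENT_J_PER_MG) {
  if (any(rates$vo2 <= 0))
    stop("contract error: vo2 must be > 0 for energetics", call. = FALSE)
  rates$rq <- rates$vco2 / rates$vo2
  rates$rq_suspect <- rates$rq < 0.6 | rates$rq > 1.1
  if (any(rates$rq_suspect))
    warning("RQ outside [0.6, 1.1] for ", sum(rates$rq_suspect),
            " record(s); retained and flagged", call. = FALSE)
  rates$mhp <- rates$vo2 * (oxyjoule[1] + oxyjoule[2] * rates$rq)
  rates$ehl <- latent_heat * rates$vh2o
  rates$ehl_mhp <- rates$ehl / rates$mhp
  rates
}

#' Mass-specific rates
#'
#' Divides the extensive rates (vo2, vco2, vh2o, mhp, ehl) by body mass.
#' Ratios (rq, ehl_mhp) are intensive and left unchanged.
#'
#' @param rates Data frame of rates (see [rates_from_fractions()]).
#' @param mass_g Body mass in grams; must be > 0.
#' @return The rates divided by `mass_g`, with a `mass_specific` attribute.
#' @export
mass_specific <- function(rates, mass_g) {
  if (!is.numeric(mass_g) || length(mass_g) != 1 || mass_g <= 0)
    stop("contract error: mass_g must be a single value > 0", call. = FALSE)
  for (k in intersect(c("vo2", "vco2", "vh2o", "mhp", "ehl"), names(rates)))
    rates[[k]] <- rates[[k]] / mass_g
  attr(rates, "mass_specific") <- TRUE
  rates
}
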