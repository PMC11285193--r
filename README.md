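# squirreltherm

Thermal physiology of small endotherms from flow-through respirometry and
body-temperature loggers.

Ecophysiologists assess how an animal copes with heat by combining two data
streams: laboratory respirometry trials, in which a resting animal's oxygen
consumption (VO2), CO2 production, evaporative water loss (EWL) and
subcutaneous temperature are measured across a staircase of ambient
temperatures; and field deployments of implanted loggers recording core body
temperature every few minutes for months. `squirreltherm` implements the
full analysis path for both — it was built around the biology of a ~60 g
nocturnal flying squirrel, but every parameter is configurable.

What it does:

* **Gas exchange.** Converts analyzer fractions and flow to rates with the
  nitrogen-balance (dilution-exact) equations, then derives RQ, metabolic
  heat production `MHP = VO2 (16 + 5.164 RQ)` J h⁻¹, evaporative heat loss
  `EHL = 2.41 VH2O` J h⁻¹, and EHL/MHP.
* **Resting-bout extraction.** For each 40-min stretch of a trial, selects
  the lowest-mean 10-min CO2 window and its most-stable 5-min sub-window,
  then applies exclusion tests (first-hour settle-in, ±1 h of disruptions,
  CO2-variability activity rule, visually labelled activity with a washout
  pad) and marks one best resting estimate per temperature step.
* **Thermoneutral-zone limits.** Fits two-segment regressions
  `y = β₀ + β₁x + (β₂−β₁)(x−ψ)₊` of VO2 (mass covariate), EWL,
  subcutaneous temperature and EHL/MHP against ambient temperature; `ψ` is
  the lower critical temperature for VO2 and the heat-response inflection
  for the rest. `fit_piecewise()` returns a classed model object with
  `print`, `summary`, `coef`, `predict`, `plot`, `confint`, `simulate`,
  `residuals` and `logLik` methods; CIs are a hybrid Wald/profile-likelihood
  interval. `test_no_breakpoint()` decides breakpoint absence by AICc (≥2
  rule).
* **Circadian body temperature.** Day/night phases from NOAA sunrise/sunset,
  dusk-to-dusk "squirrel dates", per-phase modes/means/ranges, the
  Heterothermy Index `HI = sqrt(Σ(T_mod − T_b,i)²/(n−1))`, torpor detection
  (< 35 °C for ≥ 30 min), cosinor period/amplitude, and AICc + Akaike-weight
  comparison of daily drivers (day of year, ambient maxima) with
  per-individual random intercepts.
* **Synthetic data.** `generate_respirometry_trial()` and
  `generate_free_ranging()` simulate both data streams with exact mass
  balance, chamber washout, activity bursts, circadian plateaus, ambient
  coupling and rare shallow torpor — with ground truth, so the whole
  pipeline is testable without deposited raw data.

## Worked example

Simulate a field season's worth of respirometry (18 trials, rotating
20–40 °C schedules, per-animal physiology drawn around population defaults),
extract resting bouts, and estimate the thermoneutral-zone limits:

```r
library(squirreltherm)

study <- simulate_respirometry_study(n_trials = 18, seed = 1)
sum(study$bouts$retained)
#> [1] 90

suite <- fit_response_suite(study$bouts)
suite
#> Thermal response breakpoints
#>   VO2 (lower critical temperature)     psi = 30.00 [29.27, 30.73] degC
#>   Evaporative water loss               psi = 36.17 [35.94, 36.40] degC
#>   Subcutaneous temperature             psi = 33.49 [33.08, 33.91] degC
#>   EHL/MHP                              psi = 36.13 [35.91, 36.36] degC
#>   Upper VO2 inflection (Ta >= 30):     no-breakpoint  (dAICc = -3.69)
```

The generator planted a lower critical temperature of 29.8 °C and an EWL
inflection at 36.2 °C; the fitted breakpoints recover both within their
confidence intervals, and the flat high-temperature VO2 is correctly read
as having no upper inflection (the two-segment model loses by 3.7 AICc
units). Each fit is a full model object:

```r
suite$vo2
#> Two-segment regression (grid)
#>   breakpoint psi = 30.000  [29.274, 30.726] (95% hybrid CI)
#>   slopes: -8.3429 (below) | 0.0007 (above);  n = 90, sigma = 6.925
```

Below the breakpoint VO2 falls by ~8.3 ml O2 h⁻¹ per °C of warming (thermal
conductance); above it the slope is indistinguishable from zero — the
classic thermoneutral plateau.

Free-ranging body temperature, 30 days at 5-min resolution:

```r
f <- generate_free_ranging(rhythm_params(), site(), n_days = 30, seed = 7)
p <- thermal_profile(f$tb, f$ta, site())
mode_binned(p$t_b[p$phase == "day"]); mode_binned(p$t_b[p$phase == "night"])
#> [1] 37.4
#> [1] 39.9

mean(daily_hi(p)$hi)
#> [1] 1.97
```

The recovered phase modes sit within one 0.1 °C bin of the generating
plateaus (37.5 °C resting by day, 39.9 °C active by night — the animal is
nocturnal), and the mean daily Heterothermy Index of ~2 °C reflects the
rest–active cycling.

`run_pipeline()` chains all stages (simulate → extract → fit → profile →
compare) under one configuration and seed, writing CSV/JSON outputs plus a
manifest of file hashes; `inst/scripts/squirreltherm-cli.R` is a thin
command-line wrapper over the same functions.

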