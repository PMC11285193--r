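---
title: "Thermal physiology from respirometry traces and body-temperature loggers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal physiology from respirometry traces and body-temperature loggers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squirreltherm)
```

`squirreltherm` analyses two kinds of data collected from small endotherms:
flow-through respirometry trials, from which it extracts resting metabolic
records and estimates the limits of the thermoneutral zone (TNZ), and
free-ranging core body-temperature logger series, from which it summarises
the circadian rhythm, heterothermy and torpor. Because raw traces of this
kind are rarely deposited, the package also contains a synthetic-data
generator that reproduces the statistical structure such studies assume, so
that every stage of the pipeline can be tested end to end against known
ground truth.

## Gas exchange from analyzer fractions

A flow-through system supplies air at a known incurrent flow (`flow`,
ml min^-1, STP-corrected) and measures fractional concentrations of O2, CO2
and water vapour in the incurrent and excurrent streams. Nitrogen is inert,
so the excurrent flow follows from the nitrogen balance,

$$\dot V_{out} = \dot V_{in} \frac{F_iN_2}{F_eN_2}, \qquad
  F N_2 = 1 - F O_2 - F CO_2 - F H_2O,$$

and the species rates from mass balance:
$\dot VO_2 = \dot V_{in} F_iO_2 - \dot V_{out} F_eO_2$ and analogously for
CO2 and water (1 ml of water vapour at STP weighs 0.803 mg). These
"dilution-exact" equations are correct when all three gases are measured
simultaneously on unscrubbed air; they are exactly the inverse of the
generator's forward model, which turns the pair into a closed oracle: at
zero noise, `rates_from_fractions()` must reproduce the generator's planted
rates to better than one part in 10^9, and the test suite checks this on a
thousand random parameter draws. The configuration assumes flow is metered
upstream (incurrent) and no scrubbing; both assumptions are isolated in
this one function.

Derived energetics use standard conversions, both overridable: metabolic
heat production $MHP = \dot VO_2\,(16 + 5.164\,RQ)$ J h^-1 (oxyjoule
coefficient) and evaporative heat loss $EHL = 2.41\,\dot VH_2O$ J h^-1
(latent heat 2.41 J mg^-1). Records with RQ outside [0.6, 1.1] are retained
but flagged.

## Extracting resting metabolic records

Trials expose an animal to a rising staircase of chamber temperatures. The
extraction follows a fixed two-stage window rule: within each 40-min
stretch of a temperature step, find the contiguous 10-min window (1,200
samples at 2 Hz) with the lowest mean CO2 signal, then within it the
contiguous 5-min window (600 samples) with the smallest standard deviation.
Ties break to the earliest start, and the implementation is required (by
test) to agree exactly with a brute-force search over all contiguous
windows. "Lowest 1,200 values" is read as the lowest-mean contiguous
window: the stable 5-min sub-window must form a period, which forces
contiguity.

Candidate windows are then screened by exclusion rules: anything
overlapping the first hour of the trial (settle-in), anything within an
hour of a logged disruption, anything whose CO2 standard deviation reaches
the activity threshold, and anything overlapping a visually labelled active
interval. The activity threshold is the minimum (configurably the mean) of
the CO2 standard deviations over labelled active intervals; with no labels
it falls back to a quantile (default 0.90) of rolling 5-min standard
deviations. One refinement matters in practice: CO2 released during a burst
of activity persists in the chamber and decays with the washout time
constant, so visual exclusions are padded *after* each interval by
`activity_pad_s` (default 1200 s, about four time constants of a small
chamber, >98% washed out). Without the pad, windows selected immediately
after a burst carry several percent of residual activity signal. Among the
retained candidates of a step, the one with the lowest mean CO2 is that
step's best estimate; stretches tile forward from each step start and a
remainder shorter than a full stretch is dropped.

## Breakpoint regression and the thermoneutral zone

The TNZ limits are breakpoints in two-segment linear models,

$$y = \beta_0 + \beta_1 x + (\beta_2 - \beta_1)(x - \psi)_+ \;
  [+ \text{covariates}] + \varepsilon,$$

fitted to the retained bouts' VO2 (with body mass as covariate),
evaporative water loss, subcutaneous temperature and EHL/MHP against
measured ambient temperature. `fit_piecewise()` uses iterative
linearization: refit with the hinge at the current breakpoint plus an
indicator term, and update the breakpoint by the ratio of the indicator and
slope-change coefficients. The iteration is local, so every fit is checked
against the global RSS profile on a 0.05-degC grid; a solve that landed on
a secondary optimum is re-polished from the grid minimiser, and
non-convergence falls back to the grid solution outright. On noiseless
two-segment data the estimator recovers the breakpoint and slopes to 1e-6.

The breakpoint is a non-regular parameter and no single first-order
confidence interval stays calibrated across signal strengths: the Wald
(delta-method) interval $\hat\psi \pm t\,SE(\hat\gamma)/|\hat\beta_2|$ is
symmetric and too short when few observations lie beyond the break, while
the 1-df likelihood-ratio (profile RSS) region is too short when strong
signal leaves the RSS profile kinked at design points (the classical
observation that the breakpoint's LR statistic does not follow a 1-df
chi-square). The default interval is therefore the smallest interval
containing both — each component covers the other's failure mode — and in
the package's own coverage simulations (500 replicates, n = 53, scatter at
the bout level the generator produces) it attains 94-95% at the nominal
95%, where each component alone sits near 92%. Pure `delta`, `profile` and
percentile `boot` intervals remain available.

Absence of a breakpoint (the expected situation for VO2 at high ambient
temperatures) is decided by small-sample AICc: the two-segment model must
beat the plain linear model by at least 2 AICc units, counting the
breakpoint and the residual variance among its parameters. Near-saturated
fits floor the RSS at a relative tolerance (1e-12 of the response's total
sum of squares) so floating-point dust in an exact fit cannot register as
likelihood gain.

Bout-level observations are treated as independent even though individuals
contribute several bouts; no correlation structure is stated for the
original analysis, and a per-individual random intercept is available in
the driver-model machinery but not applied here. This is a known
simplification.

## Model comparison

`aicc()` implements $-2\ell + 2k + 2k(k+1)/(n-k-1)$ and `akaike_weights()`
the normalised relative likelihoods with min-subtraction for overflow
safety. For daily body-temperature summaries, `compare_tb_models()` fits
each candidate predictor set (default: intercept-only, day of year, daily
maximum ambient temperature, and both) as a linear mixed model with a
per-individual random intercept, by maximum likelihood (not REML) so
likelihoods are comparable across fixed-effect structures. The parameter
count k is fixed effects + residual variance + random-intercept variance;
AICc rankings are sensitive to this convention, so it is stated here and in
the function documentation. With a single individual the models reduce to
ordinary least squares.

## Free-ranging body temperature

Each logger record is phase-labelled day or night by sunrise and sunset at
the study site, computed with the NOAA solar position algorithm (tested
against an independently coded low-precision ephemeris to within 2
minutes); day is the half-open interval [sunrise, sunset). Records also
receive a dusk-to-dusk "squirrel date" — the date D such that the timestamp
falls in [sunset(D), sunset(D+1)) — so that a nocturnal activity period is
analysed as one unit. Polar latitudes (|lat| >= 66.5) are rejected up
front, and day-of-year covariates assume the deployment does not span a
year boundary. Ambient records are matched nearest-in-time with ties to the
earlier record and a 45-min gap cutoff.

Per squirrel-date and phase, the summaries are the binned mode (0.1 degC
bins, ties to the lower bin centre — the logger's resolution scale; the
original analysis does not state its binning), mean, SD, min, max and
range. The Heterothermy Index is the root-mean-square deviation from a
modal reference temperature with an n-1 denominator,
$HI = \sqrt{\sum_i (T_{mod} - T_{b,i})^2/(n-1)}$; the reference is the
individual's deployment-wide active-phase mode, chosen over a daily mode
for stability on 5-min data. Torpor bouts are maximal runs below 35 degC
lasting at least 30 min (a deliberately conservative floor relative to the
hour-scale bouts reported for this system; both threshold and duration are
configurable), with sampling gaps splitting candidate runs.

The published analysis extracted daily period and amplitude with a
nonstationary waveform method; that exact algorithm is out of scope here
and is replaced by a cosinor: $T_b(t) = M + A\cos(2\pi(t-\phi)/\tau)$ with
the period profiled over 0.5-1.5 days in 0.01-day steps and amplitude
reported as peak-to-trough ($2A$), estimated per squirrel date from a
centred 3-day window. On a pure cosine this is exact; on the plateau-shaped
rhythms real animals produce, the cosinor's fundamental sits near the lower
edge of the wavelet-based amplitudes reported for such data (the package's
simulations give ~3.1 degC where the generator's daily max-min span is
~3.5-4.4), which is the expected behaviour of a first-harmonic estimator
and the main cost of the stand-in.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults describe a ~60 g
nocturnal flying squirrel at the northern edge of its range and were fixed
from the study system and field norms before any recovery test was run:

* Physiology: TNZ metabolic rate 90 ml O2 h^-1 (~1.5 ml g^-1 h^-1 at the
  60.6 g mean mass), lower critical temperature 29.8 degC with slope
  -9 ml h^-1 degC^-1 below it (metabolism about doubles by 20 degC),
  evaporative water loss 55 mg h^-1 inflecting at 36.2 degC with
  +45 mg h^-1 degC^-1 above, subcutaneous temperature 36.5 degC inflecting
  at 33.64 degC with slope 0.55, RQ 0.85. No upper metabolic inflection is
  present in the default forward model, matching the absence the analysis
  is meant to confirm.
* Trials: 2 Hz sampling (the 1,200-samples-in-10-min arithmetic of the
  window rule), single-compartment exponential chamber washout with a
  300-s time constant (chamber volume is never stated for such systems, so
  this is a free parameter), multiplicative activity bursts (factor 2.5,
  ~2 h^-1, 1-5 min) so the activity-SD exclusion has signal to detect,
  analyzer white noise of 2e-5 on each fraction, and per-trial biological
  variation: mass N(60.6, 8.1) g with ^0.75 allometric scaling and 8%
  lognormal jitter on metabolic and evaporative levels. Excurrent fractions
  come from the exact mass balance above.
* Rhythm: rest/active plateaus 37.5/39.9 degC with 60-min cosine ramps
  centred on sunrise/sunset, a post-dusk overshoot (+0.5 degC), pre-dawn
  bump (+0.3) and late-rest dip (-0.8) that reproduce the daily min/max
  structure of field loggers without moving the binned modes, AR(1) noise
  with stationary SD 0.3 degC (coefficient 0.7 at 5-min steps), rest-level
  coupling of 0.04 degC per degC of daily maximum ambient anomaly, a
  -0.0022 degC/day seasonal trend, and rare shallow torpor (probability
  0.0025 per day, to 34.6 degC for 120 min, inserted in the rest phase).
  Ambient temperature is a diurnal sinusoid (mean 18, half-amplitude 6,
  peak 15:00) with AR(1) day-level weather (SD 3 degC).

Setting the rhythm's `noise_sd = 0` switches the field generator fully
deterministic (weather and fine noise included) so exactness checks — modes
equal to the plateaus, torpor boundaries recovered sample-exactly — are
meaningful.

What the generator does not emulate: humidity-dependent evaporation
physics, behavioural thermoregulation and nest microclimate, seasonal
acclimatisation, analyzer drift, and multi-animal chambers. Passing
recovery tests therefore demonstrates that the estimators invert the
assumed data-generating structure at realistic noise, not that field data
satisfy that structure.

## Numerical choices

Half-open interval conventions are used throughout (windows, day phase,
squirrel dates). Rolling window statistics use cumulative sums (O(n)) and
are tested for exact agreement with brute-force search. The breakpoint
iteration converges at |change| < 1e-4 degC with a 50-iteration cap and a
0.05-degC profile grid; grid and iterative routes must agree within one
grid step. Modal temperatures round to 0.1-degC bin centres with ties to
the lower centre. Constant (aliased) covariates receive coefficient 0
rather than NA. All randomness is seeded; a run's configuration and seed
are hashed into every output file, and the pipeline derives per-stage seeds
from the global seed so stages can be re-run in isolation.

The test suite's simulation sizes — 500-seed coverage and recovery runs at
n = 53 bouts, 1,000-series oracle comparisons, 200-seed driver-model
recovery at 90 squirrel-days, 18-trial studies — mirror the scale of the
study the package models and keep the full suite within a few minutes on a
single core.

## Limitations

The cosinor period/amplitude is a stand-in for the published waveform
method, as discussed above. Modal temperatures at 0.1-degC resolution are
one-bin sensitive to within-phase structure (the active-phase mode of noisy
simulated deployments lands on 39.9-40.0). Repeated measures within
individuals are ignored in the breakpoint fits. The EHL/MHP breakpoint of
the synthetic forward model coincides with the EWL inflection by
construction, so its recovery checks internal consistency rather than an
independent quantity. Logger gaps are retained as missing and never
interpolated, which biases nothing but reduces n for daily summaries.
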