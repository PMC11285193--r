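Package: squirreltherm
Title: Thermal Physiology of Small Endotherms from Respirometry and Body-Temperature Loggers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing flow-through respirometry trials and
    free-ranging body-temperature logger series from small endotherms.
    Extracts resting metabolic bouts from gas-analyzer traces using a
    lowest-and-most-stable window rule with settle-in, disruption and
    activity exclusion tests; converts gas fractions to oxygen consumption,
    carbon dioxide and water production by nitrogen-balance equations and
    derives metabolic heat production and evaporative heat loss; estimates
    thermoneutral-zone limits by two-segment (breakpoint) regression with
    delta-method or bootstrap confidence intervals and AICc-based tests for
    breakpoint absence; and summarises circadian core body temperature
    (day/night phase assignment from solar events, dusk-to-dusk dates,
    per-phase modes, Heterothermy Index, torpor detection, cosinor rhythm
    amplitude) with mixed-model comparison of environmental drivers.
    Includes a synthetic-data generator reproducing the statistical
    structure of such studies so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
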