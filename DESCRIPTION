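Package: oculokit
Title: Saccadic Eye-Movement Analysis for Pediatric Pro/Antisaccade Cohorts
Version: 0.1.0
Authors@R: person("Oculomotor", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for overlap pro/antisaccade experiments in
    child cohorts: saccade detection from 1000 Hz gaze traces, trial validity
    gating and classification (correct, inhibitory error, express, corrected),
    reciprocal-latency and main-sequence metrics, LATER recinormal latency
    fitting by Kolmogorov-Smirnov minimisation with an early-saccade race
    unit, reciprobit coordinates, and a group/covariate statistical stage
    (random-intercept mixed models, proportion GLMs, Bonferroni contrasts,
    age-curve and stepwise clinical-factor models). A synthetic cohort
    generator with configurable group, age and clinical-covariate effects
    drives testing and parameter-recovery studies without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
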