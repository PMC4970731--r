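# oculokit

Saccadic eye-movement analysis for pediatric pro/antisaccade cohorts.

Overlap pro/antisaccade tasks are a standard probe of processing speed and
inhibitory control in children, including clinical groups such as
childhood-onset epilepsy. A child fixates a central cross; a target appears
at ±8° while the cross stays on. On prosaccade (PS) trials the child looks
at the target; on antisaccade (AS) trials, away from it. A reflexive glance
at the target on an AS trial is a prosaccade error (PE), which may be
corrected by a secondary saccade within 300 ms. `oculokit` implements the
complete analysis chain for such experiments, for oculomotor and clinical
researchers who have per-trial gaze or saccade-event data (or need a
simulated cohort to validate a pipeline):

- **Synthetic cohort generator** — three groups (healthy control, chronic
  epilepsy, controlled epilepsy) with realistic covariates, LATER-race
  latencies, main-sequence kinematics, latency-dependent AS errors,
  corrections, blinks and configurable group/age/clinical effects.
- **Event processing** — gaze CSV and ASC-like parsing, Savitzky–Golay
  velocity, threshold saccade detection with blink handling, and the trial
  validity gate (central fixation at onset, blink-free response window).
- **Trial classification** — first valid saccade (amplitude ≥ 1°, SRT in
  [80, 1000] ms), PS/AS correctness, express flags (SRT in [80, 120] ms),
  error-correction detection.
- **Metrics** — reciprocal SRT (promptness, Hz), gain, peak velocity, and a
  per-child main-sequence regression evaluated at 8°.
- **LATER model** — recinormal latency fitting by minimisation of the
  one-sample Kolmogorov–Smirnov statistic, with an early-saccade race unit
  (`sigma_e`) and reciprobit coordinates.
- **Group statistics** — random-intercept mixed models on trial-level
  outcomes, GLMs on child-level proportions, Bonferroni pairwise contrasts,
  quadratic age curves, stepwise epilepsy-factor models, Spearman and
  R²-change associations.

## The model at the core

Promptness `p = 1000/SRT` (Hz) follows the LATER law: the main decision
unit rises at a rate `N(mu, sigma^2)`, racing an early unit `N(0,
sigma_e^2)`; observed promptness is the larger rate, conditioned positive:

    F(p) = [ Phi((p - mu)/sigma) * Phi(p/sigma_e) - G(0) ] / (1 - G(0))

Parameters minimise the KS sup-distance between `F` and the empirical CDF
(grid search + Nelder–Mead, deterministic). On a reciprobit plot a pure
recinormal sample is a straight line; the early unit adds the
short-latency express limb.

## Worked example

```r
library(oculokit)
cfg <- sim_config(n_per_group = c(HC = 10, chronic = 5, controlled = 5),
                  seed = 42)
sim      <- simulate_cohort(cfg)                    # children, trials, events
labels   <- classify_trials(sim$trials, sim$events) # gate + classify
measures <- cohort_measures(labels)                 # per-child aggregates
cohort   <- build_cohort_table(measures, sim$children)
rep <- make_report(cohort)
subset(rep$summary, measure %in% c("error_rate", "corrected_rate", "es_rate"))
```

```
          measure      group  n   mean     sd
37     error_rate         HC 10 0.4312 0.1280
38     error_rate    chronic  5 0.6848 0.0867
39     error_rate controlled  5 0.4319 0.0880
40 corrected_rate         HC 10 0.8819 0.0863
41 corrected_rate    chronic  5 0.8373 0.0837
42 corrected_rate controlled  5 0.6597 0.1954
43        es_rate         HC 10 0.0991 0.0457
44        es_rate    chronic  5 0.2095 0.1157
45        es_rate controlled  5 0.0816 0.0489
```

Chronic patients commit more inhibitory errors (0.68 vs 0.43), controlled
patients correct fewer of them (0.66 vs 0.88) — the group structure the
generator was configured with, recovered by the classification pipeline.
A per-child LATER fit of the prosaccade latencies:

```r
ps <- labels[labels$status == "valid" & labels$class == "PS_correct" &
             labels$child_id == "C001", ]
fit_later(1000 / ps$srt_ms)
#> LATER fit (KS minimisation): mu = 6.276 Hz, sigma = 1.588 Hz, sigma_e = 0.000 Hz
#>   KS = 0.1097 on n = 28
```

`mu` is the child's mean promptness (≈ 160 ms median latency), `sigma` its
between-trial variability. The full pipeline (simulate → classify →
metrics → later → stats → report) also runs behind one entry point:

```sh
Rscript inst/cli/oculokit.R all --out run1 --seed 7
```

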