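---
title: "oculokit: models, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oculokit: models, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculokit)
```

## The problem

Overlap pro/antisaccade tasks probe processing speed, saccade dynamics and
inhibitory control in children. A child fixates a central cross; a target
appears at ±8° while the cross stays on. On prosaccade (PS) trials the
instruction is to look at the target; on antisaccade (AS) trials, to look
to the mirror location. A reflexive glance at the target on an AS trial is
a prosaccade error (PE) — an inhibitory failure — which may be corrected
by a secondary saccade. `oculokit` implements the full analysis chain for
such an experiment (detection, gating, classification, metrics, latency
modelling, cohort statistics) together with a synthetic cohort generator
so that every stage is testable without real recordings.

## The LATER latency model

Saccadic reaction time (SRT) is modelled through its reciprocal,
promptness $p = 1000/\mathrm{SRT}$ (Hz), which under the LATER model is
Gaussian: a decision signal rises linearly to a threshold at a rate drawn
from $\mathcal{N}(\mu, \sigma^2)$. Very short-latency (express) saccades,
here SRT in [80, 120] ms, are carried by a second unit racing the first.
We use the conventional early-unit construction: rate
$\mathcal{N}(0, \sigma_E^2)$, observed promptness the maximum of the two
rates, draws with both rates non-positive rejected. The CDF is

$$F(p) = \frac{\Phi\!\big(\tfrac{p-\mu}{\sigma}\big)\,
\Phi\!\big(\tfrac{p}{\sigma_E}\big) - G(0)}{1 - G(0)}, \qquad p > 0,$$

with $G$ the unconditioned product; $\sigma_E = 0$ disables the early unit
and leaves the truncated main Gaussian. Parameters are estimated exactly
as the classic SPIC workflow does: by minimising the one-sample
Kolmogorov–Smirnov statistic, here with a deterministic coarse grid
(default 25 points per parameter over $\mu \in (0,20]$,
$\sigma \in (0,10]$, $\sigma_E \in [0,20]$ Hz) followed by Nelder–Mead
refinement (tolerance $10^{-4}$ in KS, no random restarts). For samples
above 2000 observations the grid stage scores a stratified subsample
(every $k$-th order statistic with its original rank); the refinement
always uses the exact statistic on the full sample. Recovery at
$n = 10^4$: $\mu$ within ~1%, $\sigma$ within ~2%, $\sigma_E$ within ~5%
of generating values in the test suite's fixed-seed runs.

Two caveats are deliberate. The model is fitted *uncensored* to data
windowed at [80, 1000] ms — whether SPIC conditions its fit on
the observation window is not documented anywhere, so we state the
approximation rather than guess. And on a reciprobit plot (probit of cumulative
probability against $-1/\mathrm{SRT}$), the early unit lifts the
short-latency limb *above* the main line: the extra express mass makes
the empirical cumulative probability at the shortest latencies larger
than the recinormal line predicts. Our tests assert that direction.

## Trial validity and classification

The operational definitions follow the field's standard rules: a valid
first saccade is the earliest horizontal movement after target onset with
amplitude ≥ 1° and SRT in [80, 1000] ms; a qualifying movement before
80 ms is an anticipation and invalidates the trial (no canonical convention exists
for whether to re-search such trials; invalidation is our documented
choice). Trials are excluded for broken central fixation
at target onset (mean gaze in the final 50 ms before onset outside 1.5°;
the rule is standard, the radius and window are our defaults since none
are canonical), for blinks overlapping the 1-s response window, and for
an optional external head-movement flag (head movements are not
observable in gaze-only files). Express bounds are inclusive on both
ends. Direction is the sign of horizontal amplitude; |amp| < 0.1° is a
tie and excludes the trial. An AS error counts as corrected when an
opposite-direction saccade of ≥ 1° (the threshold for primary saccades,
applied to corrections as well) starts within 300 ms of the error offset.
PS-task direction errors are excluded rather than analysed — they are too
rare to support inference.

## Detection

The detector is an EyeLink-parser-like velocity threshold algorithm,
because recordings of this kind typically arrive pre-parsed by the
vendor's online algorithm:
instantaneous velocity from a Savitzky–Golay-style local linear slope
(default 5-sample window at 1000 Hz; raw differencing is far too noisy),
candidate events where |v| ≥ 30 deg/s for ≥ 4 ms with peak acceleration
≥ 8000 deg/s², boundaries extended outward to where |v| falls below a
third of the threshold. All thresholds are exposed. Blink gaps split the
trace; no event may span one.

## The synthetic cohort: a stated world

The generator's defaults describe one fixed reference cohort: 48
healthy controls (HC), 15 medicated chronic and 11 unmedicated controlled
epilepsy patients; 30 PS + 30 AS trials each at ±8°, 1000 Hz; per-group,
per-task LATER parameters, per-task gain means, main-sequence kinematics
$v = 30\,a + 94.6$ deg/s (expected 334.6 deg/s at 8°, noise SD
30 deg/s), group error rates 0.36/0.65/0.48, correction probabilities
0.90/0.79/0.65 with delays U(100, 250) ms, and matching covariate
distributions (age centred near 13 years, patient IQ, onset, duration and
seizure-recency laws per group). Values neither stated nor derivable were chosen once as
field-realistic and not revisited: between-child SD of the promptness
mean 0.5 Hz and of the velocity intercept 20 deg/s (they give the mixed
model its random-intercept variance), blink rate 0.04 and fixation-break
rate 0.02 per trial (the real invalid-trial mix is not reported),
fixation jitter as an AR(1) process with stationary SD 0.05° (white
jitter at 1000 Hz would swamp any velocity threshold; real fixational
noise is strongly autocorrelated).

AS errors arise mechanistically: each AS trial draws a reflexive-unit
promptness; the error probability is logistic in that promptness with
slope 0.5 per Hz and an intercept calibrated at configuration time so
the expected error rate equals the group's target. One promptness trait
per child shifts all task means jointly, so children with a faster
reflexive rise show both more express saccades and more errors — the
express/error coupling — without asserting any mechanism beyond shared
promptness. Covariate effects (age, onset, duration, IQ, CBCL) enter
linearly on generator parameters, matching the linear/quadratic models
fitted downstream; the age–velocity effect may be quadratic with a
configurable peak.

Waveforms are minimum-jerk sigmoids scaled so the peak instantaneous
velocity equals the planned main-sequence value (duration
$D = 1.875\,A/V$). What the generator does *not* emulate: vertical or
torsional components, pupil dynamics, drift/calibration error, head
movement. A green round-trip test therefore establishes that the
detector and classifier recover what the event model encodes — not that
they would survive every artefact of real recordings.

## Metrics and statistics

Per child: mean promptness, gain (|amplitude|/8) and peak velocity per
saccade type; a per-child OLS of peak velocity on |amplitude| evaluated
at 8° (missing below 5 trials — no canonical cut-off exists, 5 is our choice); error rate over valid AS trials; corrected rate over
errors; express rate over correct PS. Child-level promptness can be
summarised either as the trial-mean of reciprocals or as the LATER
$\mu$; both are computed and the trial-mean is what the summary table
reports. AS and PE LATER parameters are fitted on pooled group data:
per-child AS/PE trial counts are too small for stable fits.

Trial-level outcomes are analysed with a two-level random-intercept
model (type × group full factorial, child random intercept), fitted by
REML via `nlme::lme` with marginal F tests. Satterthwaite denominator
degrees of freedom are not available offline, so containment df — the
closest documented SPSS-like contract — are used. Pairwise group
contrasts within saccade type are Bonferroni-adjusted over the family of
3. Child-level proportions and parameters are analysed *untransformed*
by linear models — the GLM-on-proportions convention of this literature,
chosen for fidelity over statistical optimality — with partial η² from
the marginal sums of squares. Curve estimation compares models forward
by F; the quadratic vertex $-b_1/(2 b_2)$ is reported.
Epilepsy factors enter forward at α-to-enter 0.05 on patient rows with
group and IQ as base covariates. Note that forward entry over three
factors retains at least one with probability ≈ 14% under the null —
that is the procedure's own false-entry rate, not a defect of the
implementation.

## Numerical and degenerate-input choices

KS fits below 10 (2-parameter) or 20 (3-parameter) observations error
out, as do all-equal samples. A fit is flagged non-converged if
refinement lands on a bound. Zero-variance outcomes raise errors rather
than silently producing singular fits; a failed `lme` fit falls back to
a child-mean linear model with a warning. The express-proportion
calibration conditions the window mass on the [80, 1000] ms validity
window — the scale on which the proportion is actually reported — and
the unconditional mass at the control parameters has a supremum of
~0.135, below the 0.14 control value: the conditional target is
attainable, the unconditional one is not. Seeds flow from a single
configuration seed; identical configurations reproduce cohorts exactly.

## Known limitations

No EDF/binary parsing; no pupil, vergence or vertical analysis; no
censored-window LATER variant; no likelihood or Bayesian fitting; real
cohort F/p values are not reproducible because the raw recordings are
unavailable — the statistical stage is validated by type-I calibration
and effect-recovery simulations instead.
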