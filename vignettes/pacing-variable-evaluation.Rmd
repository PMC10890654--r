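---
title: "Evaluating pacing variables in multi-stage marathon running"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating pacing variables in multi-stage marathon running}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacemetrics)
```

## The measurement problem

Pacing — how a runner distributes speed over a race — is usually
summarized by a single per-race statistic, but the literature uses many
different ones. Whether a statistic is worth using depends on three
properties that can only be assessed when the same runners repeat the
same race: *reliability* (day-to-day stability), *concurrent validity*
(agreement with the accepted reference, the coefficient of variation of
lap speeds), and *sensitivity* (ability to separate performance
levels). Multi-stage events — the same marathon run on consecutive days
on the same loop course — provide exactly that design, and this package
implements the corresponding analysis pipeline end to end.

## Data model and its assumptions

A race is an ordered vector of lap times on a loop course modeled as
`n_laps` *equal* laps of `total_distance / n_laps` metres (default:
42,195 m as 33 laps of 1278.64 m). Real lap lengths are only
approximately equal (33 × 1279 m = 42,207 m ≠ 42,195 m), and we resolve
that inconsistency by construction: all seven pacing variables are
ratios of speeds, so under equal laps they depend only on the lap
times, and the unknown true lap length cancels. Mean speed is the only
variable carrying the distance unit, and it uses the official total
distance.

Within a lap, speed is assumed constant (linear interpolation of
cumulative time in distance). This is the finest resolution split data
support and matters only for the two segment variables whose boundary
falls inside a lap: the mid-race split (boundary at `D/2`) and the
32-10 split (boundary at `D − 10,000` m).

## The variables and our conventions

Per race, with lap speeds `v_k` and time-weighted mean speed `v̄`:

* **CV** `= 100·sd(v_k)/v̄`. The sd uses the sample (n−1) denominator —
  the default of every mainstream statistics package, and the natural
  choice when a race's 33 laps are treated as a sample of the runner's
  pacing behaviour.
* **CS** `= mean(100·(v_k − v̄)/v̄)`. Note this is *always ≥ 0*: the
  arithmetic mean of lap speeds can never fall below the time-weighted
  mean (laps you run slowly occupy more time), with equality only for a
  perfectly even race. CS is therefore a (weak) variability measure,
  not a direction measure.
* **CSF** averages the percent change of every lap relative to lap 1,
  with lap 1 contributing zero; we read "mean of all lap percentages"
  as including that zero term.
* **ACS** `= mean(100·|v_k − v̄|/v̄)`; the mean absolute deviation is
  never larger than the sd, so ACS ≤ CV for every race.
* **PR** = positive range + negative range
  `= 100·(max v − min v)/v̄`.
* **MRS** and **32-10** compare two distance segments' mean speeds.

**Sign convention.** CSF, MRS and 32-10 compare an earlier with a later
segment. The package defaults to *slowdown-positive*:
`100·(early − late)/early`, so a positive pacing profile (slowing)
yields positive values; this matches the positive magnitudes these
variables take in field cohorts where nearly everyone slows. The
literal reading of "change of X in relation to Y" would flip the sign;
`sign_convention = "literal"` provides it. The choice affects signs
only, never magnitudes, and drops out of all correlation-based analyses
up to sign.

## Profile classification

Each race's profile is the OLS regression of lap speed on lap index
1..n. The Pearson correlation `r` (identical whether the predictor is
lap index or cumulative distance, since laps are equal) is thresholded
at ±0.1: inside the closed interval `[-0.1, 0.1]` the profile is even,
below it positive, above it negative. We read the threshold interval as
*inclusive* at the boundaries so classification is a total function of
`r`. A race with zero lap-speed variance has no defined correlation; it
is reported as even with `r = 0` and flagged degenerate. Perfectly
linear profiles (`|r| = 1`) are clamped to 0.999999 before the Fisher-Z
transform, with a warning.

Day-to-day profile stability is summarized two ways: the fraction of
runners keeping one label across all days (and across all but one day),
and a one-way repeated-measures ANOVA on the Fisher-Z transformed
coefficients (subjects = runners, within factor = day).

## Reliability battery

For each variable, the runners × days matrix (complete runners only)
feeds:

* **RM-ANOVA** — the two-way decomposition (subjects + days), F =
  MS_days/MS_error on df (k−1, (n−1)(k−1)). No sphericity correction is
  applied: with four days and twenty subjects the plain F is the
  convention in performance-reliability work, and the day effect is a
  secondary hypothesis here. A zero-error matrix is handled explicitly
  (F = 0 when the day effect is also zero, infinite F with a warning
  otherwise).
* **ICC(3,1)** — two-way mixed effects, single measures, *consistency*:
  `(MS_subjects − MS_error) / (MS_subjects + (k−1)·MS_error)`, with the
  standard F-based closed-form 95% CI. We default to the consistency
  form because in a multi-day race a small uniform day effect (weather,
  cumulative fatigue) should not count against a variable's
  reliability; the absolute-agreement ICC(2,1) is available by option
  for users who want day shifts penalized.
* **SEM** `= pooled sd × sqrt(1 − ICC)`, with the pooled sd computed
  over all cells after removing day means — consistent with the
  consistency ICC, so a constant day shift inflates neither ICC's
  denominator nor SEM.
* **Typical-error CV%** — RM-ANOVA on `100·ln(x)`; the square root of
  the error mean square is the typical error in log-units, and
  `100·(exp(s/100) − 1)` back-transforms it to a percent. Variables
  that can go non-positive (CS, MRS, 32-10 under negative splits)
  cannot be log-transformed; they automatically fall back to the
  raw-scale typical error over the grand mean and are flagged
  `transform_used = "raw"`. A blanket claim that all percentage
  variables can be log-transformed is not tenable in general, so the
  flag travels with the estimate.

ICC bands: poor < 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤ excellent.
No multiple-testing correction is applied across the eight per-variable
ANOVAs; they are descriptive, parallel analyses, not a joint test.

A variable whose matrix has spread at rounding-noise scale (range below
`1e-10` relative) is flagged degenerate rather than fed into the ICC,
which would otherwise be numerically undefined.

## Validity, sensitivity, groups

Concurrent validity is the per-day Pearson correlation of each variable
with CV; sensitivity is the per-day correlation of CV, ACS and PR with
mean speed. The poorly reliable variables (CS, CSF, MRS, 32-10) are
excluded from the sensitivity battery by default — carrying an
unreliable instrument into a sensitivity analysis only adds noise — but
can be re-included by argument. Correlation bands: small 0.10,
moderate 0.30, large 0.50 (on |r|).

Performance groups are Fast/Medium/Slow by mean marathon time over all
days. "Visual binning" of a scatter plot is not reproducible, so the
default cuts at explicit boundary times (4:01:17 and 4:37:08, the
printed limits of the motivating event's groups; a runner exactly on a
boundary goes to the faster group), with rank-tertiles as the
general-purpose fallback (extra runners assigned to the faster groups,
ties broken by runner id — for 20 runners: 7/7/6). Group differences
use a one-way ANOVA per (variable, day) with eta squared and Fisher's
LSD post-hoc: pairwise t statistics on the pooled within-group mean
square and its df, p-values deliberately *unadjusted* — that is what
the LSD procedure is.

## The synthetic cohort generator

Real multi-stage results live on race-timing websites; the generator
produces cohorts with the statistical structure the analyses assume so
the whole pipeline is testable offline. Lap speeds follow

```
v[r,d,k] = B_r · (1 + δ_rd) · (1 + s_r·(k − (L+1)/2)/L) · (1 + ε_rdk) · spurt_k
```

with per-runner base speed `B_r ~ N(2.72, 0.32²)` m/s truncated above
1 m/s, day effect `δ_rd ~ N(0, 0.01²)`, linear drift `s_r ~ N(−0.10,
0.04²)` (start-to-finish proportional change, *constant across days* —
encoding stable individual profiles; an option redraws it daily for
null testing), lap noise `ε` with sd `0.055·(2.72/B_r)^1.5` (slower
runners noisier), and a 3% end-spurt multiplier on the last two laps.
Defaults reflect the motivating cohort: twenty recreational-to-trained
runners at ~2.7 m/s whose lap-speed CV lands in the 5–8% band, with
predominantly positive profiles. Where the event data fix a value
(cohort size, days, speed mean/sd) we use it; where they do not (noise
level, coupling exponent, spurt size) we chose values once that produce
realistic CV levels and the observed qualitative couplings, and they
are not tuned thereafter.

What the generator does *not* emulate: cumulative multi-day fatigue,
weather, drafting and tactical interaction, non-linear (parabolic)
pacing shapes beyond the end spurt, age/sex structure, and heavy-tailed
lap-time outliers (toilet stops, falls). Tests passing on synthetic
cohorts therefore validate the *estimators* under the stated model, not
the field behaviour of real runners.

First-order planning approximations accompany the generator:
`expected_within_race_cv()` combines lap noise and drift spread
(`100·sqrt(cv² + s²·(L²−1)/(12L²))`, ignoring spurt and coupling), and
`expected_ms_icc()` predicts the mean-speed ICC from the variance
components (`σ_B² / (σ_B² + μ²σ_day² + μ²cv²κ/L)`, with κ a
second-order correction for the noise coupling). Both are documented
approximations used in parameter-recovery tests, not exact moments.

## Numerical choices and edge cases

* Non-positive or non-finite lap times are rejected at parse time with
  the offending row named; duplicate (runner, day, lap) rows are an
  error; runner-days without contiguous laps 1..n are dropped with a
  warning listing them.
* Evaluation statistics use complete runners only (present on all
  days); the pipeline filters them before any analysis.
* Degenerate inputs are contracts, not accidents: zero-variance
  profiles, zero-error ANOVA matrices, and zero-spread variables each
  have a specified, tested behaviour (see above).
* Generated lap speeds that sample non-positive are redrawn (bounded at
  100 retries); base speeds are redrawn until above 1 m/s. At the
  default parameters neither bound is ever approached.
* All randomness flows from the single seed in `synthetic_config()`;
  identical configurations produce byte-identical cohort CSVs.

## Problem sizes in the test suite

The suite exercises the estimators at the study's native scale (20 × 4
× 33) for pipeline behaviour, 1,000 random races for the metric
inequalities, 200 runners for ICC parameter recovery, and 50 seeds for
the sign test of the CV-vs-speed coupling; random ANOVA matrices up to
12 × 6 are checked against a brute-force sum-of-squares oracle at 1e−9
relative tolerance. These sizes give Monte-Carlo error comfortably
below the asserted tolerances while keeping the default test run fast.

## Limitations

* The equal-lap assumption is a modeling choice; if a real course's
  final lap is short, the segment variables (MRS, 32-10) shift
  slightly.
* ICC confidence intervals use the classical closed form, which assumes
  normality and balance; with n = 20 they are indicative, not exact.
* The typical-error CV% for percentage-valued variables depends on the
  transform convention; conventions differ across published tables, so
  cross-study comparison of that column should be qualitative.
* The sensitivity analysis treats days separately; a mixed model pooling
  days would gain power but answers a different question than per-day
  sensitivity.
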