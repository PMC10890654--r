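# pacemetrics

Pacing analysis for long-distance running from per-lap split times, built
for multi-stage (multi-day) races where the same runners repeat the same
marathon on consecutive days — the one setting where the *test–retest
reliability* of pacing statistics can actually be measured in the field.

## The problem

Studies of marathon pacing compress a whole race into a single
variability statistic, but different studies use different statistics,
and until recently nobody had checked whether those statistics are
reliable (stable when the same runner repeats the race), valid
(agreeing with the accepted reference measure), or sensitive (able to
separate faster from slower runners). `pacemetrics` implements the full
evaluation pipeline: it computes the commonly used pacing variables from
lap splits, classifies each race's pacing profile, and runs the
reliability / validity / sensitivity battery across days.

## The statistics

For a race of `n` laps with lap speeds `v_k` and race mean speed
`v̄ = total distance / total time`:

| Variable | Definition |
|---|---|
| MS | race mean speed, `D / T` (m/s) |
| CV | `100 · sd(v_k) / v̄` — coefficient of variation, the reference ("gold standard") variability measure |
| CS | mean of `100 (v_k − v̄)/v̄` — signed change in mean speed (always ≥ 0) |
| CSF | mean percent change of each lap relative to the first lap |
| ACS | mean of `100 |v_k − v̄|/v̄` — absolute change in mean speed |
| PR | pace range: fastest-lap % above `v̄` plus slowest-lap % below `v̄` |
| MRS | percent speed change between the two race halves |
| 32-10 | percent speed change between the first `D − 10 km` and the last 10 km |

CSF, MRS and 32-10 use a slowdown-positive sign convention by default
(early-segment speed minus late, over early), so positive pacing
(slowing) scores positive; a `"literal"` convention flips it.

Pacing profiles come from the OLS regression of `v_k` on lap index:
Pearson `r` in [−0.1, 0.1] is an *even* profile, `r < −0.1` *positive*,
`r > 0.1` *negative*. The day-comparison ANOVA runs on Fisher-Z
transformed coefficients.

The reliability battery per variable: repeated-measures ANOVA (day
effect), ICC(3,1) with a 95% CI (two-way mixed, single measures,
consistency; ICC(2,1) optional), SEM = pooled sd × √(1 − ICC), and the
typical-error CV% via the `100·ln(x)` transform and back-transform
`100·(exp(s/100) − 1)`. Validity is the per-day Pearson correlation of
each variable with CV; sensitivity is the correlation with MS plus a
Fast/Medium/Slow one-way ANOVA with unadjusted LSD post-hoc tests and
eta squared.

Because real multi-stage race data are scraped from event websites, the
package ships a seeded synthetic-cohort generator
(`synthetic_config()` / `generate_cohort()`) whose defaults emulate the
motivating event: 20 runners × 4 days × 33 laps of a ~1279 m loop, base
speed 2.72 ± 0.32 m/s, ~5.5% lap noise, stable per-runner linear drift
(mean −10% start-to-finish), small day effects, slower-runner noise
coupling and a 3% end spurt over the last two laps.

## Worked example

```r
library(pacemetrics)

# a 3-lap toy course with lap speeds 4, 5, 6 m/s
toy <- race_course(total_distance = 3000, n_laps = 3)
tt  <- 1000 / c(4, 5, 6)
pacing_cv(tt, toy); pacing_acs(tt, toy); pacing_range(tt, toy)[["pr"]]
#> CV 20.56   CS 2.78   ACS 14.63   PR 41.11   MRS -31.25
```

The race mean speed is 4.865 m/s (time-weighted, not the arithmetic
mean 5), so the lap speeds deviate by −17.8%, +2.8% and +23.3%; the sd
of the lap speeds (exactly 1) over the mean speed gives CV = 20.56%,
and PR is the sum of the extreme deviations, 41.11%.

```r
out <- generate_cohort(synthetic_config(seed = 42))
pv  <- pacing_variables(out$cohort)
reliability_report(pv)
#>   variable cv_percent    sem   icc icc_ci_low icc_ci_high  icc_band
#> 1       ms       1.17 0.0305 0.995      0.990       0.998 excellent
#> 2       cv      14.77 0.9594 0.690      0.501       0.843  moderate
#> 3      acs      16.34 0.8403 0.655      0.456       0.823  moderate
#> 4       pr      18.81 4.7251 0.643      0.441       0.816  moderate
#> ... (cs, csf, mrs, split_32_10 rows omitted)

profile_consistency(pacing_profiles(out$cohort))$summary
#>   n_runners frac_all_days frac_all_but_one frac_other
#> 1        20           0.8             0.15       0.05

sensitivity_correlations(pv)   # CV/ACS/PR against mean speed, per day
#>   variable day      r  p_value  n interpretation
#> 1       cv   1 -0.879 3.44e-07 20          large
#> 2       cv   2 -0.706 4.98e-04 20          large
#> ...
```

Read as: mean speed repeats almost perfectly across days (ICC 0.995,
SEM 0.03 m/s); the pacing variables are noisier (moderate ICCs here);
80% of the synthetic runners keep the same profile label on all four
days; and within-race variability correlates negatively with speed —
slower runners pace less evenly.

The one-shot pipeline writes the whole report bundle (metrics,
profiles, consistency, reliability, validity, sensitivity, group
comparison, run log) as CSV/text/JSON:

```r
run_pipeline(synthetic_cfg = synthetic_config(seed = 7), out_dir = "report")
```

or from a shell, `Rscript inst/cli/pacemetrics.R --synthetic --seed 7 --out report`
(use `--input splits.csv` for real data: long-format CSV with columns
`runner_id, day, lap, lap_time_s`).

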