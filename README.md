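# dehprecon

Reconstruction of di(2-ethylhexyl) phthalate (DEHP) intake — the *timing* and
*magnitude* of individual exposure events — from urinary biomonitoring time
series, for exposure scientists and biostatisticians working with full-void
study designs (every urination of every subject timed, volumed, and assayed
for the four DEHP metabolites MEHP, MEHHP, MEOHP and MECPP).

## What it does

**Forward model.** Per metabolite, a two-compartment first-order excretion
model on a 15-min event grid: a bolus dose of `d` µg/kg contributes
`f_m · (d·BW/MW_DEHP) · MW_m` µg of metabolite to an appearance pool (rate
`k_a`), which feeds the body pool, which drains into the bladder at the
elimination rate `k_m = ln 2 / t½`; a void empties the bladder and the
predicted concentration is bladder mass over void volume. Updates use the
exact exponential solution (no step error; mass conserved to rounding).
Defaults: MEHP `f = 0.059`, `t½ = 5 hr` (the calibrated values); MEHHP/MEOHP/
MECPP `f = 0.149/0.109/0.132`, `t½ = 10/10/12 hr` (reference literature
values, config-exposed).

**Inverse procedure.** An automated replacement for fitting by eye:
sequentially detect voids whose concentrations exceed the running model's
prediction (≥ 2 metabolites rising by ≥ 5 µg/L and ≥ 1.2-fold), fit one
event per detected window by grid search over time × log-spaced magnitude
with a weighted `log1p` SSE loss (MEHP down-weighted 0.25), refine each event
with the others fixed, and prune events below 1 µg/kg. Deterministic given
data and configuration.

**Reporting.** Person-day intake tables and bins, hourly intake profiles,
nighttime (2200–0500) summaries, diary concordance (±60 min), broom-style
`tidy()`/`glance()` and `autoplot()`.

**Sensitivity analyses.** Dose spreading over 2/8/24 hr in 15-min
sub-boluses, ±2 hr bolus shifts, series difference metrics, and a
creatinine-correction spot-sample intake comparison (`spot_intake()`,
`compare_daily()`).

**Synthetic cohorts.** `generate_cohort()` draws a realistic 8-subject ×
7-day study (~427 voids, 0–4 events/day of 1–60 µg/kg, nighttime events,
diary-anchored meals, lognormal noise, LOD censoring) with ground truth, so
every stage is testable end to end.

## Worked example

```r
library(dehprecon)
library(dplyr)

coh <- generate_cohort(cohort_config(), seed = 1)
coh
#> Synthetic DEHP biomonitoring cohort
#>   8 subjects x 7 days = 56 person-days; 383 voids, 90 true events (seed 1)

v1  <- filter(coh$voids, subject_id == "s1")
fit <- reconstruct_subject(v1, metabolite_specs(), body_weight_kg = 70)
fit
#> DEHP dose reconstruction -- subject s1
#>   49 voids over 7 day(s); 10 events kept, 1 pruned (< 1 ug/kg)
#>   daily intake: mean 17.45, median 21.27 ug/kg-day
#>   observed-vs-predicted r: MEHP 0.979, MEHHP 0.972, MEOHP 0.980, MECPP 0.983

tidy(fit) |> filter(kept) |> select(time_min, dose_ug_kg) |> head(3)
#> # A tibble: 3 × 2
#>   time_min dose_ug_kg
#>      <dbl>      <dbl>
#> 1      405       7.67
#> 2     1380      17.1
#> 3     2055       8.84

truth <- filter(coh$events, subject_id == "s1")
sum(truth$dose_ug_kg); sum(filter(tidy(fit), kept)$dose_ug_kg)
#> [1] 124.3
#> [1] 122.2

nighttime_summary(filter(tidy(fit), kept), n_person_days = 7)
#> # A tibble: 1 × 4
#>   n_events n_night_events night_ug_kg_day night_fraction
#> 1       10              1            2.44          0.140
```

Reading the output: subject s1's week is explained by 10 retained exposure
events; the reconstructed weekly intake (122.2 µg/kg) recovers the generator's
truth (124.3 µg/kg) within 2% under 20% measurement noise, and per-metabolite
observed-vs-predicted correlations are ≈ 0.97–0.98. One fitted event of 2.4
µg/kg-day (14% of intake) falls in the 2200–0500 nighttime window. Under
these realistic conditions — doses down to 1 µg/kg, multiple events per
inter-void gap, long overnight gaps — total intake is recovered much more
reliably than individual event *times*; on well-separated events ≥ 3 µg/kg
the procedure recovers every event exactly (noise-free) or within ±2 hr (20%
noise), as the test suite verifies.

Plots: `autoplot(fit)` (observed vs predicted series per metabolite),
`plot_hourly_profile(hourly_profile(events, n_person_days))`.

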