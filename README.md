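# circafeed

Circadian rhythms and diurnal patterns in individual-animal hourly feed
intake.

## What this is for

Electronic feeding stations (EFS) record every feeder visit of every pig in
a pen — identity, timestamps, and the weight of feed removed — yielding
months of hourly intake per individual. `circafeed` is an analysis pipeline
for such data, aimed at researchers in animal behaviour and precision
livestock farming who want to separate two dimensions of circadian
organisation in feeding:

* **circadian rhythm** — whether intake repeats on an ~24 h cycle at all,
  detected per animal per day by a Morlet continuous wavelet transform with
  white-noise surrogate significance;
* **diurnal pattern** — the within-day shape of intake (timing of peaks,
  night fasting, day-to-day consistency), described per animal per 14-day
  period by a two-part hurdle generalised additive model.

The pipeline covers visit cleaning and hourly aggregation, welfare-day
filtering, LOESS de-trending with 7-day amplitude correction, wavelet
detection, hurdle-GAM fitting with likelihood-ratio model comparisons,
extraction of eight diurnal features, and cohort statistics: period-effect
mixed models with AR(1) residuals, pen/pig intraclass correlations, and
per-period Spearman association matrices. A synthetic-cohort generator
with known ground truth backs every stage's tests.

## The models in brief

Hourly intake `y` is zero-inflated: the hurdle model factorises it as

    P(y > 0)        = pi(hour, day)      (binomial GAM, logit link)
    E(y | y > 0)    = mu(hour, day)      (gamma GAM, log link)
    predicted intake = pi * mu

with each surface a cyclic cubic spline in hour (8 knots, one smooth per
14-day period) plus a trend spline in day (4 knots). This is
likelihood-equivalent to a zero-adjusted gamma model; the hurdle form makes
the two likelihood factors separable.

For rhythm detection, the de-trended, amplitude-corrected series `x(t)` is
transformed with the Morlet wavelet (omega_0 = 6) at periods 8–48 h;
wavelet power at each (time, period) pixel is compared with 1000 Gaussian
white-noise surrogates, and a day counts as circadian when the median
surrogate p-value over the 23.5–24.5 h band across its 24 time points is
below 0.05.

Consistency of a feature `f` across periods is summarised by the
intraclass correlations of a mixed model
`f ~ period + (1|pen) + (1|pig)` with AR(1) residuals:
`ICC = var_component / (var_pig + var_pen + var_resid)`.

## Worked example

```r
library(circafeed)

# simulate two pens of three pigs: alternans and single-peak day feeders
# plus an inconsistent night feeder, 42 days
spec <- cohort_spec(n_pens = 2, pigs_per_pen = 3, n_days = 42, seed = 7)
cohort <- simulate_cohort(spec, profiles = list(profile_alternans(),
                                                profile_single_peak(),
                                                profile_night_feeder()))

# clean the visit records and aggregate back to hourly series
cl <- clean_visits(cohort$visits, cleaning_rules())
hourly <- aggregate_hourly(cl$visits, n_days = 42,
                           removed_pig_days = cl$removed_pig_days)

# wavelet detection, hurdle GAMs, features, statistics
res <- run_pipeline(hourly, n_sim = 1000, seed = 7)

# proportion of days with a circadian rhythm, per pig
vapply(res$calls, function(cc) mean(cc$is_circadian[cc$evaluable]), 0)
#> pig001 pig002 pig003 pig004 pig005 pig006
#>   1.00   0.93   0.43   0.95   1.00   0.48
```

Pigs 3 and 6 are the programmed night feeders (low day-to-day consistency):
they show a circadian rhythm on under half of their days, while the
consistent day feeders are rhythmic nearly every day.

```r
head(res$features[, c("pig_id", "period_id", "n_peaks", "peak_time_h",
                      "peak_height", "night_prop", "max_prob_eat",
                      "prop_circadian_days")])
#>   pig_id period_id n_peaks peak_time_h peak_height night_prop max_prob_eat prop_circadian_days
#> 1 pig001         1       2        17.0         238    0.01963        0.834               1.000
#> 2 pig001         2       2        16.8         313    0.00851        0.845               1.000
#> 3 pig001         3       3        17.2         395    0.02469        0.869               1.000
#> 4 pig002         1       1        16.6         300    0.01325        0.935               1.000
#> 5 pig002         2       2        16.5         387    0.04163        0.743               0.786
#> 6 pig002         3       1        16.0         585    0.02786        0.943               1.000
```

One row per pig-period: pig 1 (alternans) keeps two intake peaks with the
highest near 17:00 whose de-trended height grows across periods as the
animal matures; its night intake share stays near zero and it eats at its
favourite hour on >83% of days. Likelihood-ratio comparisons confirm the
diurnal splines earn their keep against a trend-only model for 100% of
these pigs, while period-specific shapes add nothing here — by design,
since the programmed profiles do not change with age:

```r
res$lr_summary
#>          reduced pct_rejected
#> 1 single_diurnal            0
#> 2     trend_only          100
```

The staged analysis in `analysis/01_simulate.R` … `analysis/06_consistency.R`
runs the same pipeline on a larger mixed cohort with injected recording
errors and welfare events, writing each stage's tables under `results/`.

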