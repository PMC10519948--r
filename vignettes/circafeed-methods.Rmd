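---
title: "Detecting circadian rhythms and describing diurnal patterns in hourly feed intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian rhythms and describing diurnal patterns in hourly feed intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circafeed)
```

## The problem

Feed intake recorded at electronic feeding stations (EFS) is one of the few
behaviours of group-housed pigs that can be measured continuously, per
individual, for months. Its use as a welfare or health indicator is limited
by large, poorly understood baseline variation. This package separates two
dimensions of that variation in hourly intake series:

* **circadian rhythm** — does the behaviour repeat on an approximately 24 h
  cycle at all, regardless of its within-day shape; and
* **diurnal pattern** — the within-day shape itself: when during the day an
  animal concentrates its intake, and how consistently it replays that shape
  from day to day.

The pipeline runs from raw visit records (animal id, entry/exit timestamps,
trough weight change) to cohort-level consistency statistics, with every
stage validated against a synthetic-cohort generator whose ground truth is
known.

## Data preparation

**Visit cleaning.** EFS hardware occasionally logs impossible visits. The
rule families are: negative intake; feeding rate above `rate_max`
(default 150 g/min); duration above `dur_max` (default 3600 s) or zero
duration with non-zero intake; overlapping visits of the same animal; and
finally removal of *all* visits of any pig-day on which more than
`day_frac_max` (default 0.25) of visits were already removed — aggregating
the survivors of such a day would bias its hourly totals downward, so the
day becomes missing rather than partially zero. All thresholds are exposed
in `cleaning_rules()` because EFS-cleaning conventions differ between labs;
the defaults follow the spirit of the published EFS-cleaning literature.
Each removed visit is counted under the first rule it violates, so the
report partitions the removals.

**Hourly aggregation.** Surviving visit intakes are summed into calendar
hour bins (bin *h* covers `[h, h+1)` hours post-midnight — a convention all
modules share). A visit spanning an hour boundary is split proportionally
to the time spent in each bin; this is the unbiased assignment and matters
little in practice since visits average a few minutes. Hours without visits
on retained days are genuine zeros; hours of removed days are missing.

**Welfare-day filters.** Because the target is *basal* behaviour, the
pipeline removes days within ±3 days (inclusive; the convention is
configurable, the inclusive reading being the cautious one) of a high
disease score, days before the first health observation (habituation and
undetected illness), and days after the first slaughter departure (social
disruption).

## Circadian detection

**Pre-processing.** Wavelet significance testing assumes roughly constant
mean and variance. Growth drives intake up several-fold across the phase,
so each pig's series is de-trended with LOESS (span 0.75, tricube weights,
locally quadratic — the default behaviour of `stats::loess`, which the
degree argument can override) fitted on the true time index so gaps stay
gaps. Amplitude drift (older pigs concentrate the same daily intake into
fewer hours) is handled by dividing each consecutive 7-day block by its
de-trended range, making every valid block span exactly one unit; blocks
whose range falls below `1e-9` pass through unscaled and are flagged.
Missing points are then replaced by zero — *not* imputed, to avoid
inventing structure — and remembered in a fill mask so that no circadian
call is ever made on a day containing invented data. Blocks are aligned to
each animal's first retained day; the alignment choice only shifts block
boundaries and was fixed once.

**Transform.** The Morlet continuous wavelet transform (central frequency
ω₀ = 6, the standard admissibility-respecting choice) is evaluated at
log₂-spaced periods covering 8–48 h with 20 voices per octave — fine
enough that at least one grid row falls inside the 23.5–24.5 h call band.
The implementation multiplies in the frequency domain after zero-padding
beyond the widest wavelet's support; a literal time-domain convolution is
kept as an independent oracle and the two agree to better than 1e−6
relative error outside the cone of influence (the edge region within
√2·scale of either end, where power is flagged unreliable). Power is the
squared modulus normalised by series variance, so it is invariant to
rescaling the input.

**Significance.** Each (time, period) pixel is compared against the same
transform applied to 1000 Gaussian white-noise surrogates of equal length;
the p-value is `(1 + #{surrogate power ≥ observed}) / (n_sim + 1)`, a valid
finite-sample estimator that cannot be exactly zero. Comparisons are
pixel-wise (pooling over time was the alternative; pixel-wise is the
stricter reading and calibrates correctly in our null tests). Because
power is variance-normalised, the surrogate ensemble depends only on the
series length, so one ensemble is shared by all animals of a cohort — this
is an exactness-preserving optimisation, not an approximation.

**Daily calls and summaries.** A day is circadian when the median p-value
over the band rows × its 24 time points is below 0.05. Proportions of
circadian days are reported per 28-day month and per 14-day period, the
latter only when at least 7 evaluable days exist. Days whose band pixels
touch the cone of influence are called but flagged, so users can exclude
record edges.

## Diurnal patterns: the hurdle GAM

Most hours contain no intake, so zeros and positive intakes are modelled
separately — the hurdle decomposition of a zero-adjusted gamma model. Both
factorise the likelihood identically; the hurdle form is used because the
two parts then share no parameters and can be maximised independently
(their log-likelihoods simply add). Per animal:

* **probability part** — eat/no-eat per hour, binomial with logit link;
* **intake part** — positive intakes, gamma with log link, with a
  per-period dispersion reported from Pearson residuals.

Each part combines a cyclic cubic spline in hour (8 knots on [0, 24], one
smooth per retained 14-day period) and a P-spline trend in day (4 knots).
The hour covariate of bin *h* is its midpoint *h* + 0.5. Periods are
consecutive 14-day blocks from the first retained cohort day, the final
partial block kept as its own shorter period; a pig-period with fewer than
7 available days is excluded. Predicted intake is the product π·μ of the
two fitted surfaces — an identity by construction, which the tests assert
to machine precision.

**Smoothing convention.** Smooths default to fixed-df regression splines
(`fx = TRUE` in `mgcv`) rather than penalised fits. The reason is the
model-comparison step: likelihood-ratio statistics between nested
fixed-df fits follow their chi-squared reference closely (empirical size
5–9% at nominal 5% across our calibration studies), whereas penalised fits with
data-driven smoothing parameters are visibly anti-conservative (about 15%
empirical size) because the effective-df difference under-counts the
selection. Penalised REML fitting remains available via
`penalized = TRUE`. Degrees of freedom for the LR test are the
effective-df difference rounded to 2 decimals, so reported statistics are
reproducible even in the penalised case.

**Known limitation.** The chi-squared calibration holds when the two-part
likelihood is correctly specified. If day-to-day profile jitter is added
on top of the binomial/gamma sampling (the generator's `consistency`
below 1), the positive part is over-dispersed relative to a gamma and the
LR test rejects a true single-pattern null at roughly twice the nominal
rate. Period-change detection power is nevertheless high (100% in our
programmed-change study), and the same caveat applies to any
gamma-likelihood-based comparison on real data.

**Reduced models.** Two nested reductions quantify whether diurnal
structure earns its keep: trend-only, and a single diurnal shape shared by
all periods. The cohort summary reports the percentage of animals for
which the full model fits significantly better.

## Features

Eight features per pig-period, all from the de-trended prediction (the
day-trend term held at its period mean, making periods comparable across
growth stages), evaluated on a 0.1 h grid (sub-6-minute timing resolution,
stable for 8-knot smooths):

1. number of peaks — derivative sign changes from increasing to
   decreasing, cyclic across midnight; plateaus count once at their first
   point;
2. timing of the highest peak (hours post-midnight);
3. height of the highest peak (de-trended g/h);
4. width of the highest peak — mean drop in height half an hour before and
   after the peak, so *larger values mean narrower peaks*; for a local
   parabola `H − a(t−t*)²` this equals `a/4` exactly, which the tests
   assert;
5. lowest intake (de-trended g/h);
6. proportion of intake at night — the integral of the curve over
   21:00–05:00 divided by the full-day integral, trapezoidal by default
   (a bin-sum mode exists for replicating hour-binned conventions);
7. minimum and 8. maximum probability of eating, taken over the period's
   full hour × day probability surface (not the single de-trended curve),
   since they proxy day-to-day consistency of eating times across the
   whole period. Taking extremes over hours only was the alternative
   reading; the full surface is used and documented.

The per-period proportion of circadian days joins the table as a ninth
column, connecting the two branches of the pipeline.

## Consistency statistics

Features are transformed toward normality before mixed modelling: square
root (lowest intake, minimum eating probability), log (peak height and
width), and a constant minus square root for peak timing. The constant
defaults to 24 — the hour-scale maximum — and is configurable because the
choice is a convention; users replicating a particular dialect should set
it explicitly. Shapiro–Wilk W ≥ 0.9 on residuals is the acceptance gate;
the gate *flags* rather than blocks, because on deliberately heterogeneous
synthetic cohorts (discrete profile groups) multimodality is expected and
informative.

Each transformed feature is modelled as
`value ~ period + (1 | pen) + (1 | pig)` with AR(1) residuals across
consecutive periods within pig. The AR(1) process is fitted as a glmmTMB
`ar1` random effect while the independent residual variance is suppressed
(`dispformula = ~0`), so the AR(1) diagonal *is* the residual variance —
matching the intraclass-correlation definition
`ICC = var_component / (var_pig + var_pen + var_resid)`. Animals missing
interior periods keep true time gaps (`correlation ρ^gap`). Optimisation
uses BFGS, which in our replicate studies converges cleanly where the
default nlminb reports spurious false-convergence; boundary fits (a
variance estimate at zero, or the AR parameter absorbing a variance
component — an identifiability limit with few periods per animal) are
returned with a `singular` flag rather than an error.

The period effect is a Wald chi-squared test on the period fixed-effect
block (LR optional), followed when significant by Tukey-adjusted pairwise
contrasts and a compact letter display computed in-package from the
adjusted p-values. Associations between all features use Spearman rank
correlation (average ranks on ties, pairwise-complete rows — the
complete-case alternative discards more data and was not chosen), with
coefficients labelled weak (< 0.4 absolute), moderate ([0.4, 0.6)) or
strong (≥ 0.6).

No multiplicity correction is applied across the per-feature period tests;
the seven tests are reported side by side as a descriptive table.

## The synthetic-data generator

`simulate_cohort()` emulates the study design the pipeline targets: 10
pens of 11 pigs monitored for 83 days (any scale is configurable), each
animal assigned a diurnal profile — alternans (small peak near 10:00,
larger near 16:00, night fasting), single afternoon peak, night feeder, or
flat — with 24 hourly eating probabilities and mean positive intakes.
Hourly intake is Bernoulli × gamma (shape 4 by default, matching the
downstream gamma model); the growth trend multiplies the mean, defaulting
to a linear ramp from 1.0 to 2.5 over the phase, the magnitude the LOESS
step is designed to remove. Day-to-day inconsistency is Gaussian jitter on
the logit of the eating probabilities and the log of the mean intakes,
scaled by `1 − consistency`, which preserves the range constraints of both
parameter vectors. Magnitudes (logit SD 2, log SD 0.8 at consistency 0)
were chosen once to span visibly rigid to visibly erratic behaviour. Pen
and pig random offsets act on the same scales. Whole days go missing with
a configurable probability, and an error injector plants negative-intake,
rate-spike and over-long-visit records to exercise the cleaning rules.

Visits are reconstructed from hourly values by splitting each non-zero
hour into 1–3 visits with dyadic fractions (1; ½ + ½; ½ + ¼ + ¼), which
are exact in binary floating point, so aggregation inverts generation
bit-for-bit — the round-trip the ingest tests assert.

What the generator does *not* emulate: feeder-queue competition (patterns
and consistency are programmed, not emergent), autocorrelated within-day
meal structure, drift of a profile with age, or weight-driven feedback on
intake. Passing tests therefore demonstrate that the pipeline recovers
what was programmed under realistic noise — not that real pigs satisfy the
model's assumptions.

## Problem sizes and numerical choices

The validation studies use sizes chosen to make Monte-Carlo error small
relative to the tolerances they check: null calibration on 20 white-noise
series with 1000 surrogates; detection power on 10 + 10 programmed
rhythm/noise animals over 28 days; profile recovery on 20 animals over
five 14-day periods; LR size on 120 period-constant animals and power on
20 programmed-change animals; ICC recovery on 200 replicate cohorts of
10 × 11 animals. Tolerances: transform cross-check 1e−6 relative;
amplitude-correction range guard 1e−9; LR statistics clamped at zero when
penalisation noise makes a nested difference marginally negative;
surrogate p-values bounded away from zero by construction.

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` re-runs the demo cohort
and all validation studies from scratch and writes their headline
quantities as JSON. The staged analysis under `analysis/` (simulate →
ingest → circadian → GAM → features → consistency) exchanges only
plain-text files under `results/` and narrates what each stage found.
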