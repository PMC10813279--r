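---
title: "Circadian actigraphy and blue-light hygiene with actilux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian actigraphy and blue-light hygiene with actilux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actilux)
```

actilux analyses week-long, epoch-level wrist actigraphy — motor activity
(PIM counts), wrist skin temperature (wT, °C), illuminance (lx) and
blue-light irradiance (µW/cm²) at 1-minute resolution — and relates circadian
light exposure to metabolic proxies such as BMI, leptin and cortisol. This
vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic cohort generator does and does not emulate.

## The data model

An `epoch_series` is a uniformly spaced, timezone-naive grid of epochs with
per-epoch validity flags. Masking is the only mechanism for excluding data:
masked epochs stay on the grid (so spacing stays uniform and clock
arithmetic stays trivial) but are excluded from every downstream mean,
variance, fit and index. Gaps in an input file are filled with masked
epochs; duplicated or off-grid timestamps are integrity errors because they
indicate a corrupt export rather than missing data. Non-wear is *not*
inferred: only explicit validity columns or grid gaps create masks, since
field studies of this kind clean artifacts against sleep diaries.

Daily profiles are built by pooling all unmasked epochs of all days into
48 clock-aligned 30-minute bins and averaging once ("pool-then-mean"). This
is robust to partial days; a per-day-first mode (`per_day = TRUE`) is
available and agrees with pooling on complete identical days. Bins without
contributors are flagged missing, never imputed.

Blue-light irradiance is log10-transformed where stated, with a positive
floor (default 0.01 µW/cm²) applied first because device zeros are common
at night and the logarithm must stay defined. The floor sits an order of
magnitude below the lowest hygiene anchor (0.1 µW/cm²) so no
recommendation-relevant level is ever clipped.

## Cosinor rhythmometry

The parametric summary is the single-component cosinor with fixed 24 h
period: least squares of
$y(t) = M + \beta\cos(2\pi t/24) + \gamma\sin(2\pi t/24)$,
reported as MESOR $M$, amplitude $A = \sqrt{\beta^2 + \gamma^2}$, and
acrophase — the local clock time of the fitted peak, printed as hh:mm
rather than negative degrees, which matches how field studies tabulate
phase. Rhythm detection uses the zero-amplitude F-test with $(2, n-3)$
degrees of freedom against the intercept-only model. A constant series is
reported as amplitude 0 with $p = 1$ by convention rather than NaN. The
period is fixed at 24 h; period estimation, multi-harmonic and
population-mean cosinor are out of scope.

## Non-parametric indices

IS and IV follow the classical hourly-means convention:
$\mathrm{IS} = N\sum_h(\bar x_h-\bar x)^2 / (24\sum_i(x_i-\bar x)^2)$
over the $N$ sequential hourly values and 24 clock-hour classes, and IV is
the mean squared successive difference of the hourly sequence divided by
its variance — exactly 2 in expectation for white noise and 4 for strict
alternation. With masked hours, successive differences are taken only over
adjacent non-missing pairs, which reduces to the textbook $N/(N-1)$ formula
on complete data. A raw-epoch basis is available behind `basis = "epoch"`.
Zero-variance input raises an explicit degenerate-data error instead of
propagating NaN.

M10 and L5 are found by exhaustive sliding-window search (10 h and 5 h) over
the wrap-around mean daily profile at the epoch resolution, with ties broken
by the earliest clock onset — deterministic, and consistent with reporting
onsets as hh:mm. RA is $(M10-L5)/(M10+L5)$, defined as 0 when both windows
are empty of signal. CFI is the mean of IS, the inverted-normalised IV
(clipped to $[0,1]$), and RA. Whether M10/L5 should be computed per day and
averaged is genuinely open in the field; the mean-profile convention is the
default here and the per-day path can be assembled from `split_days()`.

## Sleep scoring

Sleep/wake is scored from 1-minute activity with a weighted moving window
(the Cole 1992 family):
$D_t = 0.001\,(106a_{t-4} + 54a_{t-3} + 58a_{t-2} + 76a_{t-1} + 230a_t +
74a_{t+1} + 67a_{t+2})$, sleep iff $D_t < 1$, zero-padded at the record
boundaries. The published weights assume a particular count magnitude, so
`scale` (default 100) converts device counts; PIM counts are
device-specific and no claim is made that the default reproduces any
proprietary software's calibration. Webster-style rescoring is not applied.

Nights are anchored on diary events (bedtime/waketime button presses) or a
configured default window — never detected automatically, matching how such
studies actually anchor rest intervals. Sleep onset is the first run of at
least `onset_rule` (default 5) consecutive sleep minutes after bedtime;
TST and WASO partition onset→waketime exactly; efficiency is
100·TST/time-in-bed; sleep phase is the clock midpoint of bedtime and
waketime (the convention consistent with published group tables). A night
with no qualifying sleep run is returned as `unscorable`, never as zeros.

## The blue-light reference curve, NEI and DDI

Three published hygiene anchors define the curve: ≥250 lx melanopic EDI
during daytime, ≤10 lx mEDI in the pre-bed evening, <1 lx mEDI during
sleep. With the D65 melanopic efficacy (1 lx mEDI = 0.13262 µW/cm²) these
become 33, 1.33 and (as printed in the source recommendations) 0.1 µW/cm²;
`medi_to_irradiance()` always returns the exact conversion while the curve
uses the printed 0.1 anchor.

The curve shape is an explicit reconstruction (the defining appendix of the
motivating study is not publicly available): a daytime half-sine arc
$P\sin(\pi(t-6)/14)$ with $P = 33/\sin(3\pi/14) \approx 52.93$ so the arc
crosses 33 µW/cm² at 09:00 and 17:00; a cosine evening ramp from 1.33 down
to 0.1 between 20:00 and 23:00; a 0.1 plateau until 05:00; and a cosine
morning ramp back to the arc. One non-obvious choice: taken literally, a
half-sine on [06:00, 20:00) tends to zero at the window edges while the
evening segment starts at 1.33, which would make the curve discontinuous
and dip below the sleep ceiling. The day arc is therefore floored at the
pre-bed ceiling, which preserves every anchor value and makes the curve
continuous with `value(t) ≥ 0.1` everywhere. All anchors and breakpoints
are arguments, and a flat-day `plateau33` preset ships as an alternative.

NEI_bl is the area of exposure *above* the curve over 20:00–05:00 (18
half-hour bins, wrapping midnight); DDI_bl the area *below* it over
06:00–20:00 (28 bins). Both use rectangle quadrature with the reference
evaluated at bin midpoints — the profile data are already bin means, so
finer quadrature would add no information; a 1-second-grid integration
oracle is used in the tests instead, exactly where the midpoint rule is
provably exact (flat-in-window references) and within an explicit
$O(\Delta^2 R'')$ bound on the curved default. Missing bins contribute zero
and are counted. Windows are half-open (`[20:00, 05:00)`), and indices are
computed on the participant's mean profile by default with a
`per_day_mean` mode.

## The association layer

The r-chart computes, for each of the 48 clock bins, the Pearson
correlation across participants between the (log10) blue-light bin value
and a scalar outcome, with a two-sided p from the t transform on $n-2$ df.
Multiplicity is handled inside the 48-bin family only, with
Benjamini–Hochberg step-up at $q = 0.1$; raw ($p<0.05$) and FDR flags are
stored independently because BH at $q=0.1$ can reject bins the raw
threshold does not. The time course of r is summarised by a cosinor fit to
the 48 (bin midpoint, r) points with its zero-amplitude test. Bins with
fewer than 4 complete pairs are not evaluable. Spearman is available behind
a flag; for a single predictor, regression-based r and correlation coincide
up to sign and scale.

The BMI-group window detector builds per-group t-based 95% confidence
intervals per bin and returns the maximal wrap-around run of bins with
disjoint intervals, ties broken by the earliest start scanning clockwise
from 12:00 (so evening windows that cross midnight stay contiguous); the
threshold curve is the upper bound of the lower-mean group inside the
window. Correlation strengths between independent groups are compared with
the Fisher z test; the dependent-correlation variants are deliberately not
implemented since genotype strata are independent samples. The
covariate-adjusted association is a thin OLS wrapper (standardized
predictor and outcome, covariates age, sex, population) that reproduces the
adjusted-table structure; stepwise selection is intentionally excluded.

## The synthetic cohort generator

No public recording of the motivating study exists, so `simulate_cohort()`
emulates its data structure: 7-day, 1-minute, 4-channel recordings for a
configurable number of participants at 66.9° N around the spring equinox
(day 80), plus a metadata table (BMI, age, sex, population, MTNR1B
rs10830963 genotype with 44% G-carriers) and hormone values. Defaults are
anchored one-time to published cohort statistics: wT cosinor MESOR 31.9 °C,
amplitude 1.4 °C, acrophase 02:45; mean bedtime 22:35 and waketime 06:51
with between-subject SDs near one hour; evening indoor light tuned so the
default cohort lands near a mean NEI_bl of ~2 µW/cm²·h, blue-light MESOR
~10 µW/cm², and r(NEI_bl, BMI) ~0.4. Distributional forms (Gaussian noise,
lognormal light) are simulator choices, not data-derived.

Planted, recoverable effects give every analysis stage a ground truth: an
evening blue-light excess of `beta_nei_bmi·(BMI−25)` µW/cm² weighted by a
raised cosine peaking at 23:30 (optionally restricted to G-allele
carriers), a G-carrier-specific wT MESOR slope in BMI, leptin generated
from BMI and the planted WASO minutes, and cortisol from the realized
DDI_bl and the participant's morning-light shift. The photoperiod module
supplies the seasonal envelope and returns explicit polar-day/night
sentinels above the Arctic circle.

What the generator does *not* emulate: ultradian activity structure,
weekday/weekend patterns, seasonal change within a record, thermoregulatory
or metabolic mechanism, device noise floors and sensor spectral error.
Passing recovery tests therefore demonstrates that the estimators are
correct and calibrated under the assumed first-order circadian structure —
not that the pipeline would reproduce any particular field cohort's values.

## Numerical and scale choices

Problem sizes in the test-suite and acceptance script are chosen to make
Monte-Carlo bands tight while staying quick on one core: 1000 replicates
for the cosinor type-I error (binomial SE ≈ 0.7%), 200 for the hourly IS/IV
expectations, 100 replicates at n = 200 for r-chart recovery and null
calibration, and a 60-participant default cohort for end-to-end summaries.
All randomness flows from a single user seed; identical config and seed
give byte-identical pipeline outputs (the manifest deliberately excludes
timestamps and the output path). Degenerate inputs fail loudly with classed
conditions (`actilux_format_error`, `actilux_integrity_error`,
`actilux_degenerate_error`, …) so callers can distinguish corrupt files,
insufficient data and undefined statistics.

## Known limitations

- Local clock time only; daylight-saving transitions inside a record are
  not handled (week-long records are assumed to avoid them).
- The reference curve is a documented reconstruction; conclusions that
  depend on its exact shape should be checked against the `plateau33`
  preset and custom anchor sets.
- The Cole `scale` default is a declared convention for PIM-like counts,
  not a validated calibration.
- Sensor spectral correction (e.g. secondary red-wavelength sensitivity of
  RGB blue channels) is out of scope; inputs are taken at face value.

## A worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(n_participants = 20, seed = 1))
s <- co$series$P001

fit_cosinor(s, "wrist_temp")
nonparametric_indices(s, "activity_pim")
light_indices(s, reference_curve())

res <- run_pipeline(list(simulate = list(n_participants = 20),
                         seed = 1, out_dir = tempfile("run")))
res$rcharts$bmi
```
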