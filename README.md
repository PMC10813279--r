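# actilux

Circadian actigraphy analysis for week-long wearable recordings: rhythm
metrics, sleep scoring, blue-light hygiene indices, and time-resolved
association of light exposure with metabolic proxies.

Modern wrist actigraphs record motor activity (PIM counts), wrist skin
temperature (wT), illuminance and blue-light irradiance at 1-minute
epochs. In populations with extreme light environments — the motivating
setting is Arctic residents around the spring equinox — the *timing* of
blue-light exposure, not just its amount, is the candidate driver of
metabolic outcomes such as BMI, leptin and cortisol. actilux implements
the full analysis chain for such studies:

- **Rhythmometry** — single-component cosinor with fixed 24 h period
  (MESOR, amplitude *A* = √(β²+γ²), acrophase as clock time of peak,
  zero-amplitude F-test), and the non-parametric rest–activity indices
  IS, IV, M10/L5 with onsets, RA = (M10−L5)/(M10+L5), and
  CFI = (IS + (2−IV)/2 + RA)/3.
- **Sleep** — Cole-style weighted-window sleep/wake scoring of 1-min
  activity (sleep iff D\_t < 1 with the published 7-epoch weights) inside
  diary-anchored rest intervals; per-night bedtime, waketime, latency,
  TST, WASO, efficiency and sleep phase (clock midpoint).
- **Light hygiene** — a recommendation-anchored 24 h blue-light reference
  curve (250 lx mEDI ≈ 33 µW/cm² by day, ≤10 lx ≈ 1.33 µW/cm² pre-bed,
  <1 lx → 0.1 µW/cm² in sleep) and the two derived areas:
  **DDI_bl**, the daytime deficit below the curve over 06:00–20:00, and
  **NEI_bl**, the nocturnal excess above it over 20:00–05:00
  (both in µW/cm²·h).
- **Association** — per-clock-bin correlation charts (r-charts) of
  log10 blue-light profiles against an outcome, Benjamini–Hochberg FDR at
  q = 0.1 within the 48-bin family, a cosinor fit to r(t) with its
  zero-amplitude test, BMI-group confidence-interval window detection
  (wrap-around), Fisher z comparison of independent correlations, and
  genotype-stratified charts (e.g. MTNR1B rs10830963 G-allele carriers).
- **Synthetic cohorts** — a generator that emulates the study's data
  structure (7-day, 1-min, photoperiod-driven light at 66.9° N) with
  planted, recoverable effects, so every estimator can be validated
  against known ground truth.

## Worked example

```r
library(actilux)

co <- simulate_cohort(sim_config(n_participants = 20, seed = 1))
s <- co$series$P001

fit_cosinor(s, "wrist_temp")
#> <cosinor_fit> period 24 h, n = 10080
#>   MESOR 31.85  amplitude 1.749  acrophase 2:45
#>   zero-amplitude F = 8.697e+04, p = 0

nonparametric_indices(s, "activity_pim")
#> <nonparam_indices> channel activity_pim (basis hourly)
#>   IS 0.969  IV 0.273  RA 0.964  CFI 0.932
#>   M10 3715 at 11:44  L5 67.99 at 2:02

li <- light_indices(s)
sprintf("DDI_bl = %.1f, NEI_bl = %.2f uW/cm2.h", li$ddi_bl, li$nei_bl)
#> "DDI_bl = 347.3, NEI_bl = 1.58 uW/cm2.h"
```

This participant has a robust wrist-temperature rhythm peaking at 02:45
with MESOR 31.85 °C, a stable and consolidated rest–activity pattern
(IS 0.97, RA 0.96), a large daytime blue-light deficit relative to the
33 µW/cm² recommendation, and a modest nocturnal blue-light excess.

The whole pipeline — per-participant table, r-charts, CI window,
stratified charts, manifest — runs from one config:

```r
res <- run_pipeline(list(simulate = list(n_participants = 60),
                         seed = 1, out_dir = "run1"))
res$rcharts$bmi
#> <rchart> 48 bins, 48 evaluable; raw-significant 3, FDR(q=0.1) 0
#>   cosinor of r(t): amplitude 0.086, acrophase 17:39, p = 0.00184
```

Here the cosinor of r(t) rejects flat association (p = 0.0018): the
correlation between BMI and blue-light exposure depends on clock time, as
expected from the planted evening effect — though at n = 60 the acrophase
of such a small amplitude is loosely determined. Identical config and seed
reproduce every output file byte for byte.

A thin command-line wrapper lives at `inst/cli/actilux-pipeline.R`:

```sh
Rscript inst/cli/actilux-pipeline.R --config run.yaml --seed 1 --out run1
```

## Documentation

The methods vignette (`vignettes/actilux-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with units and
defaults, the reference-curve reconstruction, what the synthetic generator
does and does not emulate, and the package's numerical conventions.
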