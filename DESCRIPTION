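Package: actilux
Title: Circadian Actigraphy, Blue-Light Hygiene Indices and Time-Resolved
    Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of epoch-level wrist actigraphy recordings carrying
    motor activity (PIM counts), wrist skin temperature, illuminance and
    blue-light irradiance channels.  Provides single-component cosinor
    rhythmometry (MESOR, 24 h amplitude, acrophase, zero-amplitude test),
    the classical non-parametric rest-activity indices (IS, IV, M10, L5,
    RA, CFI), Cole-style sleep/wake scoring with per-night sleep summaries,
    a recommendation-anchored blue-light reference curve with the daytime
    deficit (DDI_bl) and nocturnal excess (NEI_bl) indices, time-resolved
    per-bin correlation charts (r-charts) with Benjamini-Hochberg FDR
    control and a cosinor fit to r(t), group confidence-interval window
    detection, genotype-stratified analyses, and a synthetic cohort
    generator that emulates week-long, 1-minute Arctic actigraphy with
    planted, recoverable effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
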