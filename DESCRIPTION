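Package: octfwhm
Title: Retinal Vessel Caliber Measurement on OCT B-Scans by Full-Width
    Half-Maximum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures retinal vessel outer and lumen diameters on
    spectral-domain optical coherence tomography (SD-OCT) B-scan images by
    sub-pixel full-width half-maximum (FWHM) edge localization on intensity
    profiles drawn perpendicularly across a vessel. Derives wall thickness
    and the arteriovenous ratio, assembles per-subject records, and provides
    the cohort statistics used to compare clinical groups: one-way ANOVA from
    raw data or from published (n, mean, SD) summaries, Fisher's LSD pairwise
    comparisons, Spearman rank correlation, and chi-square/Fisher contingency
    tests. Ships a synthetic-data module that simulates vessel cross-section
    profiles, speckle-corrupted pseudo-B-scans, and whole cohorts with stated
    group distributions, so the full pipeline is testable without clinical
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
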