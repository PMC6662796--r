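# octfwhm

Retinal vessel caliber measurement on SD-OCT B-scans by full-width
half-maximum (FWHM) edge localization, with the cohort statistics used to
compare the resulting structural parameters between clinical groups.

Retinal arterioles and venules are the only microvessels that can be
inspected directly in vivo, and their calibers track systemic
cardiovascular risk. On a spectral-domain OCT B-scan, a vessel cut
perpendicular to its axis shows two hyper-reflective wall bands flanking
the darker blood column. This package is for researchers who want to turn
such images into quantitative structural parameters:

* **RAOD / RVOD** — arterial / venular outer diameter (µm),
* **RALD / RVLD** — arterial / venular lumen diameter (µm),
* **AWT / VWT** — wall thickness, `(outer − lumen) / 2`,
* **AVR** — the per-subject arteriovenous ratio,

and then into group comparisons (one-way ANOVA with Fisher's LSD pairwise
tests, chi-square / Fisher covariate tables, Spearman rank correlation with
a disease-severity grade).

## The method

An intensity profile is sampled by bilinear interpolation along a scan line
placed perpendicularly across the vessel on a 1 µm/px isotropic image. The
two most prominent wall features are detected on a lightly smoothed copy of
the profile and, for each wall flank, the boundary is placed where the
profile crosses

    baseline + (extremum − baseline) / 2

at sub-pixel precision (linear interpolation between bracketing samples,
crossing nearest the extremum). With anterior-wall crossings (aL, aR) and
posterior-wall crossings (pL, pR):

    outer diameter = pR − aL        lumen diameter = pL − aR
    wall thickness = (outer − lumen) / 2

One-way ANOVA is also available directly from published per-group
`(n, mean, SD)` triples:

    SS_B = Σ nᵢ(mᵢ − m̄)²,  SS_W = Σ (nᵢ − 1)sᵢ²,
    F = [SS_B/(k−1)] / [SS_W/(N−k)]

so published summary tables can be re-analyzed without subject-level data.

A synthetic module generates PSF-blurred, speckle-corrupted vessel
profiles and pseudo-B-scans with exact ground truth, and whole cohorts
drawn from stated group distributions, so the entire pipeline is testable
without clinical images.

## Worked example

Simulate a speckled arteriole (true outer 150 µm, lumen 112 µm, 4 µm PSF,
speckle SNR 10) and a venule, measure both, and form the AVR:

```r
library(octfwhm)

sim <- make_profile(synth_vessel_spec(noise_model = "speckle",
                                      noise_param = 0.1, seed = 42))
artery <- measure_vessel(sim$profile, "artery")
artery
#> # A tibble: 1 × 5
#>   kind   outer_um lumen_um wall_um n_repeats
#> 1 artery    151.0    110.6    20.2         1

vein_sim <- make_profile(synth_vessel_spec(true_outer = 184, true_lumen = 153,
                                           noise_model = "speckle",
                                           noise_param = 0.1, seed = 43))
vein <- measure_vessel(vein_sim$profile, "vein")
compute_avr(artery, vein)
#> [1] 0.7229343
```

The measured diameters sit within ~1.5 µm of the generator's ground truth;
the AVR is the per-subject lumen ratio (110.57 / 152.94).

Re-analyze a published summary table — here the packaged arterial lumen
diameters of the three study groups (ischemic heart disease n = 91,
microvascular angina n = 29, controls n = 66):

```r
rald <- dplyr::filter(vessel_group_summaries(), parameter == "RALD") |>
  dplyr::rename(label = group)
fit <- anova_from_summary(rald)
fit
#> One-way ANOVA (summary data): F(2, 183) = 3.934, p = 0.02124

lsd_pairwise(rald)
#> # A tibble: 3 × 6
#>   group1 group2  difference std_error statistic p_value
#> 1 IHD    MA           -2.02      3.00    -0.673 0.502
#> 2 IHD    control      -6.36      2.28    -2.80  0.00573
#> 3 MA     control      -4.34      3.14    -1.38  0.168
```

The F of 3.934 (p = 0.021) says the three groups differ in arterial lumen
diameter; the LSD comparison locates the difference between the IHD and
control groups (−6.4 µm, p = 0.006), with the microvascular-angina group
intermediate.

End-to-end, `run_reproduction(out_dir, seed)` simulates a cohort at the
packaged group distributions, writes the three analysis tables, the
summary-statistic ANOVA reproduction, the enrollment counts and a JSON run
log — byte-identical for a fixed seed.

## Package layout

* `R/imaging.R` — image I/O (PNG/TIFF/BMP), isotropic resampling, zone-B
  geometry
* `R/fwhm.R` — profile extraction and the FWHM measurement core
* `R/cohort.R` — AVR, eye selection, enrollment, subject records
* `R/stats.R` — summary/raw ANOVA, LSD, Spearman, contingency tests
* `R/synth.R` — synthetic profiles, B-scans and cohorts
* `R/analyze.R`, `R/reproduce.R` — cohort analysis tables and the
  reproducible end-to-end run
* `inst/scripts/octfwhm.R` — thin CLI (`measure`, `simulate`, `analyze`,
  `reproduce`)
* `vignettes/fwhm-methods.Rmd` — methods and design notes
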