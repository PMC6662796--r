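---
title: "Measuring retinal vessel walls on OCT B-scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel walls on OCT B-scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octfwhm)
library(dplyr)
```

## The measurement problem

On a spectral-domain OCT B-scan, a retinal arteriole or venule cut
perpendicularly shows two hyper-reflective wall bands flanking the darker
blood column. The quantities of clinical interest are the outer diameter
(outer wall edge to outer wall edge; RAOD for arteries, RVOD for veins), the
lumen diameter (inner edge to inner edge; RALD / RVLD), the derived wall
thickness

$$\mathrm{AWT} = \frac{\mathrm{RAOD} - \mathrm{RALD}}{2}, \qquad
  \mathrm{VWT} = \frac{\mathrm{RVOD} - \mathrm{RVLD}}{2},$$

and the per-subject arteriovenous ratio (AVR), the ratio of the arterial to
the accompanying venular caliber. Manual caliper placement on the B-scan is
poorly repeatable, so the package localizes vessel edges on an intensity
profile by the full-width half-maximum (FWHM) criterion: each wall boundary
is placed where the profile crosses the level halfway between the wall's
intensity extremum and its local baseline, with sub-pixel precision.

The pipeline is: calibrate and resample the image to an isotropic 1 µm/px
grid (`load_oct_image()`, `resample_isotropic()`); sample a manually placed
scan line perpendicular to the vessel by bilinear interpolation
(`extract_profile()`); detect the two wall features and their half-maximum
crossings (`detect_wall_features()`, `half_max_crossings()`); report
diameters (`measure_vessel()`), averaged over repeated scans
(`average_repeats()`). Measurements are taken in zone B, the annulus between
one and one-and-a-half disc diameters around the optic disc
(`disc_geometry()`, `zone_b_contains()`), where vessel segments are
straight, rarely crossing, and large enough to resolve. The right eye is
used when gradable, otherwise the left (`select_eye()`).

## The FWHM measurement in detail

An extracted profile is min–max normalized to $[0, 1]$. Wall polarity is
auto-detected: if the two most prominent features of the profile are
intensity *minima* (dark walls, as some display conventions produce), the
profile is inverted so that walls are always maxima downstream; the decision
is recorded in the profile's `polarity` attribute.

**One smoothed measurement profile.** All downstream quantities — the two
wall extrema, the baselines, and the half-maximum crossings — are read from
a single lightly smoothed copy of the profile (Gaussian, SD
`smooth_sigma = 2` sampling steps, i.e. 0.5 µm at the default 0.25 µm step).
Two facts make this safe and necessary:

* a symmetric unimodal kernel leaves the half-maximum crossing of a
  symmetrically blurred step exactly where it was, so the edge estimate is
  not biased on clean data (the boxcar-exactness tests confirm recovery
  within one sampling step);
* the alternative — searching the raw samples — interacts badly with
  speckle: the crossing *nearest the extremum* is taken by design (to avoid
  capture by neighbouring vessels), and on raw speckled samples the first
  noisy dip below threshold systematically wins, biasing diameters inward
  by an order of 10 µm at speckle SNR 5. Smoothing at ~1/8 of the
  point-spread width removes that failure mode while adding negligible
  blur of its own. `smooth_sigma = 0` restores the raw-sample behaviour.

**Feature detection.** Local maxima of the measurement profile are ranked
by topographic prominence; the two most prominent (ties broken by larger
separation) become the anterior and posterior walls, and must bracket an
interior minimum, the lumen. Candidates below `min_prominence = 0.05`
(normalized units) are ignored; fewer than two survivors raises a
`no_vessel` error rather than guessing.

**Extremum and baseline estimation.** The wall extremum is *not* taken as
the pointwise maximum: the argmax of a noisy profile sits on the largest
upward noise excursion, which biases the half-maximum threshold upward and
drags both crossings toward the wall centre (about 0.5 µm per boundary at
SNR 5). Instead a quadratic is fitted over the feature's "cap" — the
contiguous samples within 20 % of its prominence below the peak — and the
fitted apex provides the extremum value and a sub-sample position. The
lumen minimum is estimated the same way with the sign flipped. Baselines
are local: on each wall's outer side the median of the outer 10 % tail of
the profile (robust to uneven illumination), on its lumen side the lumen
minimum.

**Crossings.** On each flank the threshold is
$\mathrm{baseline} + (\mathrm{extremum} - \mathrm{baseline}) / 2$ and the
boundary is the threshold crossing nearest the extremum, located by linear
interpolation between the two bracketing samples (verified against a
dense-grid brute-force search to $10^{-6}$ µm). A candidate crossing must
stay below threshold for about 1 µm (`2 * smooth_sigma` samples) — a
transient dip narrower than the blur cannot be a vessel boundary. Flanks
that never cross raise a `boundary` error.

**Validity domain.** Half-maximum edge localization on a blurred boxcar is
exact while the blur kernel fits inside the wall band. For the ~19 µm walls
simulated here that means Gaussian PSFs up to roughly σ = 4 µm (or compact
kernels narrower than the wall), which covers retinal SD-OCT optics. Beyond
that the criterion itself leaves the edge — with σ = 8 µm the outer
diameter reads ~4 µm high — so wall-resolving optics are a prerequisite,
not a tuning matter. The residual inward bias of the outer diameter at
speckle SNR 5 is about −1 µm (and about +0.8 µm outward for the lumen),
within one sampling pixel of the 1 µm/px source grid.

## The synthetic test bed

`make_profile()` renders a vessel cross-section as a piecewise-constant
template — background 0.15, wall bands at 1.0 spanning
$[c - o/2,\, c - l/2]$ and $[c + l/2,\, c + o/2]$, lumen plateau 0.35 —
convolved with a Gaussian PSF. The convolution is evaluated analytically as
a sum of scaled normal CDFs, so there is no discrete-convolution edge
artefact and the ground-truth edges stay exactly defined. The boxcar-plus-
blur model reproduces the rounded, parabola-like wall peaks of real
profiles while keeping truth well-posed; a literal parabola template would
have no unambiguous edge to recover. Defaults (150 µm outer, 112 µm lumen,
4 µm PSF) emulate a typical arteriole at the measurement zone. Speckle is
modelled as multiplicative gamma noise with unit mean and coefficient of
variation `noise_param` (SNR = 1/`noise_param`), the standard surrogate for
coherent-imaging speckle; additive Gaussian noise is also available.
`make_bscan()` embeds the same template as a straight tube in a 2-D image
with per-pixel noise and records the ideal perpendicular scan line, so the
2-D extraction path can be checked against the 1-D generator (they agree to
< 1 % RMS) and oblique scans can be shown to foreshorten by the secant of
the off-angle.

What the generator does *not* emulate: depth attenuation, shadowing beneath
the blood column, vessel curvature and taper, neighbouring tissue layers,
eye-motion artefacts, and speckle correlation structure (per-sample
independent speckle at 0.25 µm spacing is *harsher* than the physical
grain, which is correlated at the PSF scale). Passing tests therefore
demonstrate correctness of the edge localization under idealized geometry
and worst-case uncorrelated noise, not clinical-grade robustness.

`make_cohort()` draws per-subject vessel parameters per group from a
bivariate normal per vessel — (outer, lumen) with correlation 0.5,
truncated to $0 < \text{lumen} < \text{outer}$ — matching stated
$(n, \bar{x}, s)$ summaries, the packaged defaults being the study's three
groups (ischemic heart disease $n = 91$, microvascular angina $n = 29$,
controls $n = 66$). The 0.5 correlation is a plausibility knob, not an
estimate; the truncation matters for the venous parameters (~8 % of mass),
and the test oracles therefore use the analytic truncated-normal moments.
Covariates are drawn independently from the packaged profile (age, sex,
diabetes, smoking, hypertension, dyslipidemia, BMI per group); no
covariate–caliber dependence is injected. Severity enters only as a
supplied ordinal grade (0 = control, 1 = MA, 2 = IHD by default); no
angiographic scoring is modelled.

## The statistical battery

`anova_from_summary()` implements the one-way fixed-effects decomposition
directly from $(n_i, m_i, s_i)$ triples:

$$SS_B = \sum_i n_i (m_i - \bar m)^2,\quad
  SS_W = \sum_i (n_i - 1) s_i^2,\quad
  F = \frac{SS_B / (k-1)}{SS_W / (N-k)},$$

which is algebraically identical to the raw-data ANOVA
(`anova_raw()` agrees to $10^{-9}$, and both agree with `stats::aov()`).
Published "mean ± SD" entries are read as $n-1$ sample SDs; that convention
is confirmed by the reproduction of the published F statistics to their
last printed digit. Degenerate inputs follow explicit contracts: zero
within-group variance yields $F = 0$ when means are equal, $F = \infty$
(p = 0) otherwise. `lsd_pairwise()` is Fisher's LSD — unadjusted pairwise
$t$ tests on the pooled within-group variance, by definition without
multiplicity correction. `spearman_rank()` is the Pearson correlation of
mid-ranks with the $t$ approximation for p; `categorical_test()` computes
the Pearson chi-square $\sum (O - E)^2 / E$ without continuity correction
and switches to Fisher's exact test when any expected count falls below 5
(the switch is recorded in the output). The Shapiro–Wilk screen
(`normality_screen()`) is reported descriptively and never gates the ANOVA.
$\alpha = 0.05$ throughout.

Two published quantities are deliberately not asserted numerically: the AVR
and VWT F statistics and the severity correlations. AVR is a per-subject
ratio, and the printed group means and SDs do not determine the
distribution of the ratio (the ratio of the printed mean lumens, 0.734, is
visibly different from the printed mean AVR, 0.798); the per-subject
severity correlations likewise cannot be recovered from summary tables.
These paths are covered by construction instead: Spearman oracle
equivalence on tied data, invariance under monotone transforms, and AVR
invariance under common rescaling. For the same reason the AVR *definition*
(lumen vs outer diameters) is configurable, defaulting to lumen calibers —
the blood-column quantity classic fundus-photography AVR measures — since
the printed values cannot disambiguate the convention.

One published entry disagrees with its own identity at the last digit: the
IHD venous wall thickness prints 15.524 while
$(184.368 - 153.321)/2 = 15.5235$; the published value was evidently
rounded from unrounded diameters, and the tests assert agreement to one
unit in the last printed digit.

## Numerical and design choices

* **Coordinates.** Pixel centre $(1,1)$ sits at physical $(0,0)$ µm;
  physical position is (index − 1) × scale. Pixel pitches are required
  inputs (flags or a YAML/JSON sidecar) — device metadata is never guessed.
* **Resampling.** Bilinear, to 1 µm/px by default, mirroring the 1:1 µm
  review display; the on-screen magnification used during acquisition is
  display-only and not modelled. Physical extent is preserved to within one
  pixel per axis; downsampling by more than 4× warns.
* **Zone-B convention.** The annulus radii default to 1.0 and 1.5 disc
  diameters measured from the disc centre; because the classic drawing can
  also be read as measured from the disc margin, `reference = "margin"`
  shifts both radii by a disc radius, and the convention is stored on the
  geometry object.
* **Scan-line sampling.** 0.25 µm step — four-fold sub-pixel sampling on
  the isotropic grid. Only straight line scans are supported: perpendicular
  line scans resolve the wall cross-section; circular peripapillary scans
  render parts of each vessel obliquely and are deliberately out of scope.
* **Determinism.** Every generator takes an explicit seed;
  `run_reproduction()` is byte-identical across runs with the same seed,
  and its JSON run log records every configuration choice (seed, AVR
  definition, correlation, group sizes) needed to reproduce a bundle.
* **Problem sizes.** The packaged validation runs use 500 speckle
  replicates for the recovery study, 10,000 simulated null cohorts for the
  type-I calibration, 1,000 cohort draws for the power comparison, and
  10,000-subject groups for the moment checks — large enough that the
  Monte-Carlo error is a small fraction of each tolerance.

## Known limitations

Superficial vessels whose upper wall merges with the inner retinal layers
violate the two-clean-walls model and inflate the outer diameter; the
generator does not reproduce this failure mode, and on such images the
prominence threshold or a `no_vessel` error is the only guard. Wall
thickness inherits the difference of two edge estimates and is accordingly
the noisiest output. The enrollment module records counts only; it does not
model the clinical exclusion criteria themselves. The CLI
(`inst/scripts/octfwhm.R`) is a thin wrapper over the exported functions,
which remain the primary interface.
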