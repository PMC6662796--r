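#' Specification of a synthetic vessel cross-section
#'
#' The synthetic vessel is two hyper-reflective wall bands flanking a lumen
#' plateau on a darker background: a piecewise-constant (boxcar) template
#' convolved with a Gaussian point-spread function and optionally corrupted
#' by additive Gaussian or multiplicative speckle noise. The boxcar keeps
#' the ground-truth edges exactly defined while the blur reproduces the
#' rounded, parabola-like wall peaks seen in real profiles.
#'
#' Defaults emulate a typical retinal arteriole in the measurement zone:
#' 150 um outer and 112 um lumen diameter, a 4 um PSF, walls at full
#' normalized contrast over a 0.35 lumen / 0.15 background floor.
#'
#' @param true_outer,true_lumen Ground-truth outer and lumen diameters (um).
#' @param center Vessel centre position along the profile (um); `NULL`
#'   places it mid-profile.
#' @param wall_contrast,lumen_level,background_level Normalized plateau
#'   intensities; walls must be brighter than lumen and background.
#' @param psf_sigma Gaussian point-spread SD (um); 0 disables blur.
#' @param noise_model `"none"`, `"gaussian"` (additive, SD `noise_param`) or
#'   `"speckle"` (multiplicative gamma with unit mean and coefficient of
#'   variation `noise_param`, the standard OCT speckle surrogate).
#' @param noise_param Noise amplitude as described above; `1/noise_param` is
#'   the speckle signal-to-noise ratio.
#' @param seed Integer seed making generation reproducible; `NULL` uses the
#'   current RNG stream.
#' @return An object of class `synth_vessel_spec`.
#' @export
synth_vessel_spec <- function(true_outer = 150, true_lumen = 112,
                              center = NULL, wall_contrast = 1,
                              lumen_level = 0.35, background_level = 0.15,
                              psf_sigma = 4,
                              noise_model = c("none", "gaussian", "speckle"),
                              noise_param = 0, seed = NULL) {
  noise_model <- match.arg(noise_model)
  check_number(true_outer, "true_outer", positive = TRUE)
  check_number(true_lumen, "true_lumen", positive = TRUE)
  if (true_lumen >= true_outer) {
    stop_octfwhm("`true_lumen` must be smaller than `true_outer`.",
                 "validation")
  }
  check_number(psf_sigma, "psf_sigma")
  if (psf_sigma < 0) {
    stop_octfwhm("`psf_sigma` must be non-negative.", "validation")
  }
  if (wall_contrast <= max(lumen_level, background_level)) {
    stop_octfwhm("Walls must be brighter than lumen and background.",
                 "validation")
  }
  if (noise_model != "none") check_number(noise_param, "noise_param",
                                          positive = TRUE)
  structure(
    list(true_outer = true_outer, true_lumen = true_lumen, center = center,
         wall_contrast = wall_contrast, lumen_level = lumen_level,
         background_level = background_level, psf_sigma = psf_sigma,
         noise_model = noise_model, noise_param = noise_param, seed = seed),
    class = "synth_vessel_spec"
  )
}

# Analytic PSF-blurred template: the boxcar template convolved with a
# Gaussian is a sum of scaled normal CDFs, so no discrete convolution (and
# no edge artefact) is involved. sigma = 0 returns the piecewise-constant
# template itself, wall bands closed on the left.
vessel_template_at <- function(x, spec, center) {
  e <- center + c(-spec$true_outer, -spec$true_lumen, spec$true_lumen,
                  spec$true_outer) / 2
  bg <- spec$background_level
  dw <- spec$wall_contrast - bg
  dl <- spec$lumen_level - bg
  if (spec$psf_sigma <= 0) {
    wall <- (x >= e[1] & x < e[2]) | (x >= e[3] & x < e[4])
    lum <- x >= e[2] & x < e[3]
    return(bg + dw * wall + dl * lum)
  }
  s <- function(a) pnorm((x - a) / spec$psf_sigma)
  bg + dw * (s(e[1]) - s(e[2])) + dl * (s(e[2]) - s(e[3])) +
    dw * (s(e[3]) - s(e[4]))
}

apply_noise <- function(values, spec) {
  out <- switch(
    spec$noise_model,
    none = values,
    gaussian = values + rnorm(length(values), 0, spec$noise_param),
    speckle = {
      shape <- 1 / spec$noise_param^2
      values * rgamma(length(values), shape = shape, rate = shape)
    }
  )
  pmax(out, 0)
}

#' Simulate a vessel intensity profile
#'
#' Generates the PSF-blurred, optionally noise-corrupted cross-section
#' profile of a [synth_vessel_spec()], together with its ground truth, for
#' end-to-end testing of the FWHM measurement.
#'
#' @param spec A [synth_vessel_spec()].
#' @param length Profile length (um); must exceed
#'   `true_outer + 6 * psf_sigma` so both tails reach baseline.
#' @param step Sampling step (um).
#' @return A list with `profile` (an `oct_profile`) and `truth` (a one-row
#'   tibble: `outer_um`, `lumen_um`, `wall_um`, `center_um`, and the four
#'   true edge positions).
#' @examples
#' sim <- make_profile(synth_vessel_spec(noise_model = "speckle",
#'                                       noise_param = 0.1, seed = 42))
#' measure_vessel(sim$profile, "artery")
#' @export
make_profile <- function(spec, length = 300, step = 0.25) {
  stopifnot(inherits(spec, "synth_vessel_spec"))
  check_number(length, "length", positive = TRUE)
  check_number(step, "step", positive = TRUE)
  if (length <= spec$true_outer + 6 * spec$psf_sigma) {
    stop_octfwhm("`length` must exceed true_outer + 6 * psf_sigma.",
                 "validation")
  }
  center <- if (is.null(spec$center)) length / 2 else spec$center
  x <- seq(0, length, by = step)
  template <- vessel_template_at(x, spec, center)
  raw <- with_seed_or_current(spec$seed, apply_noise(template, spec))
  profile <- new_profile(x, raw, step = step)
  truth <- tibble(
    outer_um = spec$true_outer, lumen_um = spec$true_lumen,
    wall_um = (spec$true_outer - spec$true_lumen) / 2, center_um = center,
    edge_outer_left = center - spec$true_outer / 2,
    edge_lumen_left = center - spec$true_lumen / 2,
    edge_lumen_right = center + spec$true_lumen / 2,
    edge_outer_right = center + spec$true_outer / 2
  )
  list(profile = profile, truth = truth)
}

#' Simulate a pseudo-OCT B-scan containing one vessel
#'
#' Embeds the 1-D vessel template as a straight tube in a 2-D image: every
#' pixel takes the template value at its perpendicular distance from the
#' vessel axis, then per-pixel noise is applied. The ground truth records
#' the ideal perpendicular scan line through the vessel centre, so that
#' profile extraction from the image can be checked against the 1-D
#' generator.
#'
#' @param spec A [synth_vessel_spec()].
#' @param size `(rows, cols)` of the image in pixels.
#' @param orientation Vessel-axis direction in degrees from the image x-axis
#'   (0 = horizontal vessel, vertical scan line).
#' @param scale Isotropic pixel pitch (um/px).
#' @param step Sampling step recorded on the ground-truth scan line (um).
#' @return A list with `image` (an [oct_image()]) and `truth` (list: `line`,
#'   a [scan_line()]; `outer_um`; `lumen_um`; `center` in um).
#' @export
make_bscan <- function(spec, size = c(256, 256), orientation = 0, scale = 1,
                       step = 0.25) {
  stopifnot(inherits(spec, "synth_vessel_spec"))
  nr <- size[1L]
  nc <- size[2L]
  theta <- orientation * pi / 180
  nv <- c(-sin(theta), cos(theta))  # unit normal to the vessel axis
  cx <- (nc - 1) * scale / 2
  cy <- (nr - 1) * scale / 2
  half <- spec$true_outer / 2 + 6 * spec$psf_sigma + 10
  # the perpendicular scan (and the vessel support) must stay inside the image
  ends <- rbind(c(cx, cy) + half * nv, c(cx, cy) - half * nv)
  if (any(ends[, 1] < 0 | ends[, 1] > (nc - 1) * scale |
          ends[, 2] < 0 | ends[, 2] > (nr - 1) * scale)) {
    stop_octfwhm("Vessel does not fit inside the requested image.",
                 "validation")
  }
  px_x <- (seq_len(nc) - 1) * scale
  px_y <- (seq_len(nr) - 1) * scale
  dmat <- outer(px_y - cy, px_x - cx,
                function(dy, dx) dx * nv[1L] + dy * nv[2L])
  template <- vessel_template_at(as.numeric(dmat),
                                 spec_centered(spec), 0)
  raw <- with_seed_or_current(spec$seed, apply_noise(template, spec))
  img <- oct_image(matrix(raw, nrow = nr, ncol = nc),
                   axial_scale = scale, lateral_scale = scale,
                   bit_depth = 16L, source_id = "synthetic_bscan")
  line <- scan_line(c(cx, cy) - half * nv, c(cx, cy) + half * nv, step = step)
  list(image = img,
       truth = list(line = line, outer_um = spec$true_outer,
                    lumen_um = spec$true_lumen, center = c(cx, cy),
                    orientation = orientation))
}

# spec copy whose centre is pinned at 0 (distances are measured from the
# vessel axis when painting a B-scan)
spec_centered <- function(spec) {
  out <- spec
  out$center <- 0
  out
}

#' Specification of a synthetic cohort
#'
#' Subject-level vessel parameters are drawn per group from truncated
#' bivariate normal distributions matching stated `(n, mean, SD)` summaries:
#' one bivariate draw for (RAOD, RALD) and one for (RVOD, RVLD), each with a
#' configurable outer-lumen correlation, truncated to `0 < lumen < outer`.
#' Clinical covariates are drawn independently to match a stated covariate
#' profile. Defaults are the packaged study summaries
#' ([vessel_group_summaries()], [covariate_profile()]).
#'
#' @param summaries Per-parameter, per-group `(n, mean, sd)` tibble in the
#'   format of [vessel_group_summaries()]; must contain RAOD, RALD, RVOD,
#'   RVLD rows.
#' @param covariates Covariate profile in the format of
#'   [covariate_profile()], or `NULL` to skip covariates.
#' @param sizes Named per-group sizes; defaults to the `n` in `summaries`.
#' @param correlation Outer-lumen correlation of the joint draws, in
#'   `[-1, 1]`; default 0.5 keeps draws anatomically plausible without
#'   asserting a measured value.
#' @param avr_definition Passed to the AVR computation (`"lumen"` default).
#' @param seed Integer seed.
#' @return An object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(summaries = vessel_group_summaries(),
                              covariates = covariate_profile(),
                              sizes = NULL, correlation = 0.5,
                              avr_definition = c("lumen", "outer"),
                              seed = NULL) {
  avr_definition <- match.arg(avr_definition)
  need <- c("RAOD", "RALD", "RVOD", "RVLD")
  if (!all(need %in% summaries$parameter)) {
    stop_octfwhm("`summaries` must cover RAOD, RALD, RVOD and RVLD.",
                 "validation")
  }
  if (!is.numeric(correlation) || abs(correlation) > 1) {
    stop_octfwhm("`correlation` must lie in [-1, 1].", "validation")
  }
  groups <- unique(summaries$group)
  if (is.null(sizes)) {
    sizes <- summaries |>
      dplyr::filter(.data$parameter == "RAOD") |>
      dplyr::select("group", "n") |>
      tibble::deframe()
  }
  if (any(sizes <= 0)) {
    stop_octfwhm("Group sizes must be positive.", "validation")
  }
  for (g in groups) {
    mo <- summaries$mean[summaries$parameter == "RAOD" & summaries$group == g]
    ml <- summaries$mean[summaries$parameter == "RALD" & summaries$group == g]
    mvo <- summaries$mean[summaries$parameter == "RVOD" & summaries$group == g]
    mvl <- summaries$mean[summaries$parameter == "RVLD" & summaries$group == g]
    if (ml >= mo || mvl >= mvo) {
      stop_octfwhm("Mean lumen diameter must be below mean outer diameter.",
                   "validation")
    }
  }
  structure(
    list(summaries = summaries, covariates = covariates, sizes = sizes,
         correlation = correlation, avr_definition = avr_definition,
         seed = seed, groups = groups),
    class = "synth_cohort_spec"
  )
}

# n draws from a bivariate normal (outer, lumen) truncated to
# 0 < lumen < outer, by rejection.
draw_vessel_pairs <- function(n, mean_outer, sd_outer, mean_lumen, sd_lumen,
                              rho) {
  sigma <- matrix(c(sd_outer^2, rho * sd_outer * sd_lumen,
                    rho * sd_outer * sd_lumen, sd_lumen^2), 2L)
  out <- matrix(NA_real_, n, 2L)
  need <- seq_len(n)
  guard <- 0L
  while (length(need)) {
    draw <- MASS::mvrnorm(length(need), mu = c(mean_outer, mean_lumen),
                          Sigma = sigma)
    draw <- matrix(draw, ncol = 2L)
    ok <- draw[, 2L] > 0 & draw[, 2L] < draw[, 1L]
    out[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
    guard <- guard + 1L
    if (guard > 1000L) {
      stop_octfwhm("Truncated draw failed to converge; check the summaries.",
                   "validation")
    }
  }
  out
}

#' Simulate a whole cohort of subject records
#'
#' @param spec A [synth_cohort_spec()].
#' @return A tibble of subject records (see [subject_record()] for columns).
#'   Severity is encoded as the supplied ordinal grade 0 = control, 1 = MA,
#'   2 = IHD.
#' @examples
#' cohort <- make_cohort(synth_cohort_spec(seed = 11))
#' dplyr::count(cohort, group)
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  grade <- c(control = 0L, MA = 1L, IHD = 2L)
  with_seed_or_current(spec$seed, {
    purrr::map_dfr(spec$groups, function(g) {
      n <- as.integer(spec$sizes[[g]])
      s <- function(param, col) {
        spec$summaries[[col]][spec$summaries$parameter == param &
                                spec$summaries$group == g]
      }
      art <- draw_vessel_pairs(n, s("RAOD", "mean"), s("RAOD", "sd"),
                               s("RALD", "mean"), s("RALD", "sd"),
                               spec$correlation)
      ven <- draw_vessel_pairs(n, s("RVOD", "mean"), s("RVOD", "sd"),
                               s("RVLD", "mean"), s("RVLD", "sd"),
                               spec$correlation)
      cov <- draw_covariates(spec$covariates, g, n)
      avr_num <- if (spec$avr_definition == "lumen") art[, 2L] else art[, 1L]
      avr_den <- if (spec$avr_definition == "lumen") ven[, 2L] else ven[, 1L]
      tibble(
        subject_id = sprintf("%s-%03d", g, seq_len(n)),
        group = g,
        age = cov$age, sex = cov$sex, diabetes = cov$diabetes,
        smoker = cov$smoker, hypertension = cov$hypertension,
        dyslipidemia = cov$dyslipidemia, bmi = cov$bmi,
        eye_used = select_eye(rep(TRUE, n), rep(TRUE, n)),
        raod_um = art[, 1L], rald_um = art[, 2L],
        rvod_um = ven[, 1L], rvld_um = ven[, 2L],
        awt_um = (art[, 1L] - art[, 2L]) / 2,
        vwt_um = (ven[, 1L] - ven[, 2L]) / 2,
        avr = avr_num / avr_den,
        severity_grade = grade[[g]]
      )
    })
  })
}

draw_covariates <- function(covariates, group, n) {
  if (is.null(covariates)) {
    return(list(age = rep(NA_real_, n), sex = rep(NA_character_, n),
                diabetes = rep(NA, n), smoker = rep(NA, n),
                hypertension = rep(NA, n), dyslipidemia = rep(NA, n),
                bmi = rep(NA_real_, n)))
  }
  row <- function(var) covariates[covariates$variable == var &
                                    covariates$group == group, ]
  num <- function(var) {
    r <- row(var)
    rnorm(n, r$mean, r$sd)
  }
  bin <- function(var) {
    r <- row(var)
    stats::runif(n) < r$count / r$n
  }
  list(age = num("age"),
       sex = ifelse(bin("male_sex"), "male", "female"),
       diabetes = bin("diabetes"), smoker = bin("smoker"),
       hypertension = bin("hypertension"), dyslipidemia = bin("dyslipidemia"),
       bmi = num("bmi"))
}
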