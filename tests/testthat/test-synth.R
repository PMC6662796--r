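test_that("generators are fully deterministic under a fixed seed", {
  s1 <- make_profile(synth_vessel_spec(noise_model = "speckle",
                                       noise_param = 0.2, seed = 99))
  s2 <- make_profile(synth_vessel_spec(noise_model = "speckle",
                                       noise_param = 0.2, seed = 99))
  expect_identical(s1$profile$intensity, s2$profile$intensity)
  b1 <- make_bscan(synth_vessel_spec(noise_model = "speckle",
                                     noise_param = 0.2, seed = 99))
  b2 <- make_bscan(synth_vessel_spec(noise_model = "speckle",
                                     noise_param = 0.2, seed = 99))
  expect_identical(b1$image$pixels, b2$image$pixels)
  c1 <- make_cohort(synth_cohort_spec(seed = 99, sizes = c(
    IHD = 6, MA = 4, control = 5)))
  c2 <- make_cohort(synth_cohort_spec(seed = 99, sizes = c(
    IHD = 6, MA = 4, control = 5)))
  expect_identical(c1, c2)
})

test_that("a zero-PSF noiseless profile is the exact piecewise template", {
  spec <- synth_vessel_spec(psf_sigma = 0)
  sim <- make_profile(spec, length = 300, step = 0.5)
  x <- sim$profile$position
  lvl <- rep(spec$background_level, length(x))
  lvl[(x >= 150 - 75 & x < 150 - 56) | (x >= 150 + 56 & x < 150 + 75)] <-
    spec$wall_contrast
  lvl[x >= 150 - 56 & x < 150 + 56] <- spec$lumen_level
  norm <- (lvl - min(lvl)) / diff(range(lvl))
  expect_equal(sim$profile$intensity, norm, tolerance = 1e-12)
})

test_that("generator specs validate their invariants", {
  expect_error(synth_vessel_spec(true_outer = 100, true_lumen = 120),
               class = "octfwhm_error_validation")
  expect_error(synth_vessel_spec(wall_contrast = 0.2, lumen_level = 0.35),
               class = "octfwhm_error_validation")
  expect_error(make_profile(synth_vessel_spec(), length = 100),
               class = "octfwhm_error_validation")
  bad <- vessel_group_summaries()
  bad$mean[bad$parameter == "RALD"] <- 200  # lumen above outer
  expect_error(synth_cohort_spec(summaries = bad),
               class = "octfwhm_error_validation")
})

test_that("noiseless blurred profiles round-trip through measure_vessel", {
  sim <- make_profile(synth_vessel_spec(psf_sigma = 3), step = 0.25)
  m <- measure_vessel(sim$profile, "artery")
  expect_equal(m$outer_um, sim$truth$outer_um, tolerance = 0.25)
  expect_equal(m$lumen_um, sim$truth$lumen_um, tolerance = 0.25)
})

test_that("profiles extracted from a B-scan match the 1-D generator", {
  spec <- synth_vessel_spec(psf_sigma = 4)
  b <- make_bscan(spec, orientation = 0)
  prof2d <- extract_profile(b$image, b$truth$line)
  len <- sqrt(sum((b$truth$line$p1 - b$truth$line$p0)^2))
  prof1d <- make_profile(spec, length = len, step = 0.25)$profile
  n <- min(nrow(prof2d), nrow(prof1d))
  rms <- sqrt(mean((prof2d$intensity[seq_len(n)] -
                      prof1d$intensity[seq_len(n)])^2))
  expect_lt(rms, 0.01)
})

test_that("right-angle rotation of image and line leaves measurements unchanged", {
  spec <- synth_vessel_spec(psf_sigma = 4, seed = 17)
  b0 <- make_bscan(spec, orientation = 0)
  b90 <- make_bscan(spec, orientation = 90)
  m0 <- measure_vessel(extract_profile(b0$image, b0$truth$line), "artery")
  m90 <- measure_vessel(extract_profile(b90$image, b90$truth$line), "artery")
  expect_equal(m90$outer_um, m0$outer_um, tolerance = 1e-6)
  expect_equal(m90$lumen_um, m0$lumen_um, tolerance = 1e-6)
})

test_that("oblique scans foreshorten by the secant of the off-angle", {
  spec <- synth_vessel_spec(psf_sigma = 3)
  b <- make_bscan(spec, orientation = 0, size = c(320, 320))
  perp <- measure_vessel(extract_profile(b$image, b$truth$line), "artery")
  # rotate the scan line 30 degrees off the perpendicular, same centre
  cen <- b$truth$center
  half <- sqrt(sum((b$truth$line$p1 - cen)^2)) / cos(pi / 6)
  dir30 <- c(sin(pi / 6), cos(pi / 6))
  oblique_line <- scan_line(cen - half * dir30, cen + half * dir30)
  obl <- measure_vessel(extract_profile(b$image, oblique_line), "artery")
  expect_gte(obl$outer_um, perp$outer_um)
  expect_equal(obl$outer_um, perp$outer_um / cos(pi / 6), tolerance = 0.5)
  expect_equal(obl$lumen_um, perp$lumen_um / cos(pi / 6), tolerance = 0.5)
})

test_that("degenerate zero-SD cohorts collapse onto the group means", {
  summ <- vessel_group_summaries() |>
    dplyr::mutate(sd = 0)
  cohort <- make_cohort(synth_cohort_spec(summaries = summ, seed = 1,
                                          sizes = c(IHD = 5, MA = 5,
                                                    control = 5)))
  rald_ihd <- summ$mean[summ$parameter == "RALD" & summ$group == "IHD"]
  expect_true(all(cohort$rald_um[cohort$group == "IHD"] == rald_ihd))
})

test_that("large simulated cohorts match the truncated-model moments", {
  # the joint draw conditions on lumen < outer, so the correct analytic
  # reference is the truncated bivariate normal, not the raw (mean, sd)
  n <- 10000
  cohort <- make_cohort(synth_cohort_spec(
    seed = 8, sizes = c(IHD = n, MA = 2, control = 2)))
  summ <- dplyr::filter(vessel_group_summaries(), group == "IHD")
  ihd <- dplyr::filter(cohort, group == "IHD")
  val <- function(p, col) summ[[col]][summ$parameter == p]
  art <- oracle_truncated_moments(val("RAOD", "mean"), val("RAOD", "sd"),
                                  val("RALD", "mean"), val("RALD", "sd"), 0.5)
  ven <- oracle_truncated_moments(val("RVOD", "mean"), val("RVOD", "sd"),
                                  val("RVLD", "mean"), val("RVLD", "sd"), 0.5)
  expect_lt(abs(mean(ihd$raod_um) - art$mean_outer),
            3 * art$sd_outer / sqrt(n))
  expect_lt(abs(mean(ihd$rald_um) - art$mean_lumen),
            3 * art$sd_lumen / sqrt(n))
  expect_lt(abs(mean(ihd$rvod_um) - ven$mean_outer),
            3 * ven$sd_outer / sqrt(n))
  expect_lt(abs(mean(ihd$rvld_um) - ven$mean_lumen),
            3 * ven$sd_lumen / sqrt(n))
  expect_equal(sd(ihd$rald_um), art$sd_lumen, tolerance = 0.05)
  expect_true(all(cohort$rald_um < cohort$raod_um))
  expect_true(all(cohort$rvld_um < cohort$rvod_um))
})

test_that("cohort summaries feed back into the summary ANOVA consistently", {
  cohort <- make_cohort(synth_cohort_spec(seed = 21))
  summ <- group_vessel_summaries(cohort)
  for (p in c("RALD", "RVOD", "AVR")) {
    col <- c(RALD = "rald_um", RVOD = "rvod_um", AVR = "avr")[[p]]
    from_summary <- anova_from_summary(
      dplyr::filter(summ, parameter == p) |> dplyr::rename(label = group))
    from_raw <- anova_raw(cohort, .data[[col]], group)
    expect_equal(from_summary$f_statistic, from_raw$f_statistic,
                 tolerance = 1e-9)
  }
})

test_that("speckle replicates at moderate noise keep diameters unbiased", {
  errs <- t(vapply(1:120, function(i) {
    sim <- make_profile(synth_vessel_spec(noise_model = "speckle",
                                          noise_param = 0.1, seed = 1000 + i))
    m <- measure_vessel(sim$profile, "artery")
    c(m$outer_um - 150, m$lumen_um - 112)
  }, numeric(2)))
  expect_lt(abs(mean(errs[, 1])), 1)
  expect_lt(abs(mean(errs[, 2])), 1)
})

test_that("cohort-level RALD ANOVA power matches the noncentral-F formula", {
  # analytic oracle: noncentral F with moments of the truncated joint draw
  summ <- vessel_group_summaries()
  groups <- c("IHD", "MA", "control")
  mom <- purrr::map(groups, function(g) {
    gi <- dplyr::filter(summ, group == g)
    val <- function(p, col) gi[[col]][gi$parameter == p]
    oracle_truncated_moments(val("RAOD", "mean"), val("RAOD", "sd"),
                             val("RALD", "mean"), val("RALD", "sd"), 0.5)
  })
  n <- dplyr::filter(summ, parameter == "RALD")$n
  mu <- purrr::map_dbl(mom, "mean_lumen")
  v <- purrr::map_dbl(mom, "sd_lumen")^2
  grand <- sum(n * mu) / sum(n)
  mse <- sum((n - 1) * v) / (sum(n) - 3)
  lambda <- sum(n * (mu - grand)^2) / mse
  fcrit <- stats::qf(0.95, 2, sum(n) - 3)
  power_expect <- 1 - stats::pf(fcrit, 2, sum(n) - 3, ncp = lambda)

  reject <- vapply(1:1000, function(i) {
    cohort <- make_cohort(synth_cohort_spec(seed = 5000 + i))
    anova_raw(cohort, rald_um, group)$p_value < 0.05
  }, logical(1))
  expect_equal(mean(reject), power_expect, tolerance = 0.03)
})
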