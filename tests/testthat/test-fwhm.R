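make_isotropic <- function(px) oct_image(px, 1, 1)

test_that("profile extraction reproduces a closed-form ramp and sample count", {
  ramp <- outer(rep(1, 30), seq(0, 1, length.out = 40))  # linear in x
  img <- make_isotropic(ramp)
  line <- scan_line(c(2, 10), c(32, 10), step = 0.5)
  prof <- extract_profile(img, line)
  # floor(L / s) + 1 samples
  expect_equal(nrow(prof), floor(30 / 0.5) + 1)
  # a ramp normalizes to a straight 0..1 line
  expect_equal(prof$intensity, seq(0, 1, length.out = nrow(prof)),
               tolerance = 1e-9)
  expect_equal(attr(prof, "polarity"), "bright")
})

test_that("diagonal extraction matches the independent per-point oracle", {
  set.seed(31)
  px <- matrix(runif(50 * 50), 50, 50)
  img <- make_isotropic(px)
  line <- scan_line(c(3.2, 4.7), c(44.1, 38.6), step = 0.4)
  prof <- extract_profile(img, line)
  len <- sqrt(sum((line$p1 - line$p0)^2))
  u <- (line$p1 - line$p0) / len
  t_um <- prof$position
  raw <- oracle_bilinear(px, line$p0[1] + t_um * u[1],
                         line$p0[2] + t_um * u[2])
  expect_equal(prof$intensity, (raw - min(raw)) / diff(range(raw)),
               tolerance = 1e-12)
})

test_that("extraction rejects out-of-bounds lines and degenerate profiles", {
  img <- make_isotropic(matrix(runif(100), 10, 10))
  expect_error(extract_profile(img, scan_line(c(1, 1), c(20, 1))),
               class = "octfwhm_error_bounds")
  flat <- make_isotropic(matrix(0.5, 40, 40))
  expect_error(extract_profile(flat, scan_line(c(1, 20), c(38, 20))),
               class = "octfwhm_error_degenerate")
  aniso <- oct_image(matrix(runif(100), 10, 10), 2, 1)
  expect_error(extract_profile(aniso, scan_line(c(1, 1), c(8, 8))),
               class = "octfwhm_error_validation")
})

test_that("dark-wall profiles are inverted so walls are always maxima", {
  sim <- make_bscan(synth_vessel_spec(seed = 12))
  inverted <- oct_image(max(sim$image$pixels) - sim$image$pixels, 1, 1)
  prof_dark <- extract_profile(inverted, sim$truth$line)
  prof_bright <- extract_profile(sim$image, sim$truth$line)
  expect_equal(attr(prof_dark, "polarity"), "dark")
  expect_equal(attr(prof_bright, "polarity"), "bright")
  expect_equal(prof_dark$intensity, prof_bright$intensity, tolerance = 1e-9)
})

test_that("wall detection finds boxcar features and rejects single peaks", {
  # two symmetric boxcars, no blur: extrema at the boxcar centres
  x <- seq(0, 100, by = 0.5)
  y <- 0.1 + 0.8 * ((x >= 30 & x <= 40) | (x >= 60 & x <= 70))
  prof <- as_oct_profile(x, y)
  feats <- detect_wall_features(prof)
  expect_equal(feats$extremum_position, c(35, 65), tolerance = 0.5)

  single <- as_oct_profile(x, 0.1 + 0.8 * exp(-(x - 50)^2 / 50))
  expect_error(detect_wall_features(single),
               class = "octfwhm_error_no_vessel")
})

test_that("small additive noise does not change the detected features", {
  sim <- make_profile(synth_vessel_spec(seed = 3))
  clean <- detect_wall_features(sim$profile)
  noisy <- make_profile(synth_vessel_spec(noise_model = "gaussian",
                                          noise_param = 0.02, seed = 3))
  perturbed <- detect_wall_features(noisy$profile)
  expect_equal(perturbed$extremum_position, clean$extremum_position,
               tolerance = 1)
})

test_that("triangle-peak crossings sit midway down the flanks", {
  x <- seq(0, 60, by = 0.25)
  h <- 12
  y <- pmax(0, 1 - abs(x - 30) / h)  # linear flanks, apex 1 at x = 30
  prof <- as_oct_profile(x, y)
  feature <- list(extremum_position = 30, extremum_intensity = 1,
                  left_baseline = 0, right_baseline = 0)
  cr <- half_max_crossings(prof, feature, smooth_sigma = 0)
  expect_equal(unname(cr), c(30 - h / 2, 30 + h / 2), tolerance = 1e-9)
})

test_that("sub-pixel crossings match the dense-grid oracle to 1e-6 um", {
  set.seed(77)
  for (i in 1:200) {
    case <- random_unimodal_profile()
    cr <- half_max_crossings(case$profile, case$feature, smooth_sigma = 0)
    expect_equal(cr[["left"]],
                 oracle_crossing(case$profile, case$feature, "left"),
                 tolerance = 1e-6)
    expect_equal(cr[["right"]],
                 oracle_crossing(case$profile, case$feature, "right"),
                 tolerance = 1e-6)
  }
})

test_that("an edge-hugging feature raises a boundary-unresolved error", {
  # a peak pinned at the profile end never recrosses on its outer side
  x <- seq(0, 20, by = 0.25)
  y <- c(seq(0.1, 1, length.out = 40), rep(1, length(x) - 40))
  prof <- as_oct_profile(x, y)
  feature <- list(extremum_position = 20, extremum_intensity = 1,
                  left_baseline = 0.1, right_baseline = 0.1)
  expect_error(half_max_crossings(prof, feature, smooth_sigma = 0),
               class = "octfwhm_error_boundary")
})

test_that("blurred-boxcar measurement recovers ground truth within a step", {
  sim <- make_profile(synth_vessel_spec(true_outer = 150, true_lumen = 112,
                                        psf_sigma = 4),
                      step = 1)
  m <- measure_vessel(sim$profile, "artery")
  expect_equal(m$outer_um, 150, tolerance = 1)
  expect_equal(m$lumen_um, 112, tolerance = 1)
  expect_equal(m$wall_um, 19, tolerance = 1)
  expect_identical(m$kind, "artery")
})

test_that("edge recovery stays within one step while the PSF is narrower than the wall", {
  # half-maximum edge localization on a blurred boxcar is exact while the
  # kernel stays inside the wall band; sigma = 4 um on a 19 um wall is the
  # practical upper end of that regime at the default 0.25 um step
  for (psf in c(0.5, 1, 2, 3, 4)) {
    sim <- make_profile(synth_vessel_spec(psf_sigma = psf), length = 400)
    m <- measure_vessel(sim$profile, "artery")
    expect_equal(m$outer_um, 150, tolerance = 0.25,
                 label = sprintf("outer at psf %.1f", psf))
    expect_equal(m$lumen_um, 112, tolerance = 0.25,
                 label = sprintf("lumen at psf %.1f", psf))
  }
})

test_that("vanishing walls give an overlap error or a vanishing thickness", {
  # as true outer -> lumen the wall band disappears; the contract allows
  # either the dedicated overlap/no-vessel error or a thickness collapsing
  # toward the blur scale
  for (eps in c(1, 0.5, 0.25)) {
    sim <- make_profile(synth_vessel_spec(true_outer = 112 + 2 * eps,
                                          true_lumen = 112, psf_sigma = 0.5),
                        length = 300)
    res <- tryCatch(measure_vessel(sim$profile, "artery"),
                    octfwhm_error = function(e) e)
    if (inherits(res, "octfwhm_error")) {
      expect_true(inherits(res, "octfwhm_error_overlap") ||
                    inherits(res, "octfwhm_error_no_vessel"))
    } else {
      expect_lt(res$wall_um, eps + 2)  # saturates at the ~1.7 um combined-kernel FWHM floor
    }
  }
})

test_that("wall-thickness identity holds exactly for every measurement", {
  set.seed(41)
  for (i in 1:20) {
    sim <- make_profile(synth_vessel_spec(
      true_outer = runif(1, 120, 200), true_lumen = runif(1, 80, 110),
      psf_sigma = runif(1, 1, 5),
      noise_model = "speckle", noise_param = 0.1, seed = i))
    m <- measure_vessel(sim$profile, "artery")
    expect_identical(m$wall_um, (m$outer_um - m$lumen_um) / 2)
  }
})

test_that("repeat averaging is the arithmetic mean and keeps the identity", {
  m <- measure_vessel(make_profile(synth_vessel_spec(seed = 2))$profile,
                      "artery")
  same3 <- average_repeats(dplyr::bind_rows(m, m, m))
  expect_equal(same3$outer_um, m$outer_um)
  expect_equal(same3$lumen_um, m$lumen_um)
  expect_equal(same3$n_repeats, 3L)

  reps <- tibble::tibble(kind = "artery", outer_um = c(148, 150, 152),
                         lumen_um = c(110, 112, 114),
                         wall_um = c(19, 19, 19), n_repeats = 1L)
  avg <- average_repeats(reps)
  expect_equal(avg$outer_um, 150)
  expect_equal(avg$lumen_um, 112)
  expect_equal(avg$wall_um, 19)

  set.seed(13)
  for (i in 1:20) {
    o <- runif(3, 130, 180)
    l <- runif(3, 90, 120)
    r <- tibble::tibble(kind = "vein", outer_um = o, lumen_um = l,
                        wall_um = (o - l) / 2, n_repeats = 1L)
    avg <- average_repeats(r)
    expect_equal(avg$outer_um, sum(o) / 3, tolerance = 1e-12)
    expect_equal(avg$lumen_um, sum(l) / 3, tolerance = 1e-12)
  }

  expect_error(average_repeats(list()), class = "octfwhm_error_input")
  mixed <- tibble::tibble(kind = c("artery", "vein"),
                          outer_um = c(150, 180), lumen_um = c(110, 150),
                          wall_um = c(20, 15), n_repeats = 1L)
  expect_error(average_repeats(mixed), class = "octfwhm_error_validation")
})

test_that("diameters are shift-, scale- and intensity-affine equivariant", {
  base <- make_profile(synth_vessel_spec(noise_model = "gaussian",
                                         noise_param = 0.03, seed = 8))
  prof <- base$profile
  m0 <- measure_vessel(prof, "artery")
  b0 <- attr(m0, "boundaries")

  shifted <- as_oct_profile(prof$position + 17.25, prof$intensity)
  ms <- measure_vessel(shifted, "artery")
  expect_equal(ms$outer_um, m0$outer_um, tolerance = 1e-9)
  expect_equal(ms$lumen_um, m0$lumen_um, tolerance = 1e-9)
  expect_equal(unname(attr(ms, "boundaries")), unname(b0) + 17.25,
               tolerance = 1e-9)

  k <- 1.7
  stretched <- as_oct_profile(prof$position * k, prof$intensity)
  mk <- measure_vessel(stretched, "artery")
  expect_equal(mk$outer_um, k * m0$outer_um, tolerance = 1e-9)
  expect_equal(mk$lumen_um, k * m0$lumen_um, tolerance = 1e-9)

  affine <- as_oct_profile(prof$position, 3.1 * prof$intensity + 0.7)
  ma <- measure_vessel(affine, "artery")
  expect_equal(ma$outer_um, m0$outer_um, tolerance = 1e-9)
  expect_equal(ma$lumen_um, m0$lumen_um, tolerance = 1e-9)
})
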