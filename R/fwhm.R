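#' Extract an intensity profile along a scan line
#'
#' Samples the image by bilinear interpolation at uniform steps from `p0` to
#' `p1`, then min-max normalizes to `[0, 1]`. Wall reflectivity polarity is
#' auto-detected: if the two dominant profile features are intensity minima
#' (walls darker than their surroundings, as in profiles where the wall
#' cross-sections appear as upward-opening parabolas), the profile is
#' inverted so that walls are always maxima downstream. The applied polarity
#' is recorded in the `polarity` attribute (`"bright"` = raw walls were
#' already maxima, `"dark"` = profile was inverted).
#'
#' @param image An isotropic [oct_image()] (see [resample_isotropic()]).
#' @param line A [scan_line()] with both endpoints inside the image.
#' @return A tibble of class `oct_profile` with columns `position`
#'   (micrometres from `p0`) and `intensity` (normalized), and attributes
#'   `step` and `polarity`.
#' @examples
#' synth <- make_bscan(synth_vessel_spec(seed = 1))
#' prof <- extract_profile(synth$image, synth$truth$line)
#' head(prof)
#' @export
extract_profile <- function(image, line) {
  stopifnot(inherits(image, "oct_image"), inherits(line, "scan_line"))
  if (image$axial_scale != image$lateral_scale) {
    stop_octfwhm("Image must be isotropic; call resample_isotropic() first.",
                 "validation")
  }
  scale <- image$lateral_scale
  len <- sqrt(sum((line$p1 - line$p0)^2))
  n <- floor(len / line$step + 1e-9) + 1L
  t_um <- (seq_len(n) - 1) * line$step
  u <- (line$p1 - line$p0) / len
  xs <- (line$p0[1] + t_um * u[1]) / scale
  ys <- (line$p0[2] + t_um * u[2]) / scale
  max_x <- (ncol(image$pixels) - 1)
  max_y <- (nrow(image$pixels) - 1)
  eps <- 1e-9
  if (any(xs < -eps | xs > max_x + eps | ys < -eps | ys > max_y + eps)) {
    stop_octfwhm("Scan line leaves the image bounds.", "bounds")
  }
  raw <- bilinear_sample(image$pixels, xs, ys)
  new_profile(t_um, raw, step = line$step)
}

#' Construct a profile from externally sampled intensities
#'
#' Builds an `oct_profile` from raw position/intensity samples (for example
#' a longitudinal grey-value curve exported from an image viewer). Values
#' are min-max normalized and wall polarity is auto-detected exactly as in
#' [extract_profile()].
#'
#' @param position Strictly increasing, uniformly spaced positions (um).
#' @param intensity Matching raw intensities (any non-degenerate scale).
#' @return An `oct_profile` tibble.
#' @export
as_oct_profile <- function(position, intensity) {
  if (length(position) != length(intensity)) {
    stop_octfwhm("`position` and `intensity` must have equal length.",
                 "validation")
  }
  d <- diff(position)
  if (any(d <= 0) || diff(range(d)) > 1e-6 * max(d)) {
    stop_octfwhm("`position` must be strictly increasing with constant step.",
                 "validation")
  }
  new_profile(position, intensity, step = d[1L])
}

# Build an oct_profile from raw (possibly unnormalized) samples: normalize,
# auto-detect polarity, and validate the sampling contract.
new_profile <- function(position, raw, step, polarity = NULL) {
  if (length(position) < 16L) {
    stop_octfwhm("A profile needs at least 16 samples.", "validation")
  }
  rng <- range(raw)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    stop_octfwhm("Profile is constant; no vessel structure to normalize.",
                 "degenerate")
  }
  y <- (raw - rng[1]) / diff(rng)
  if (is.null(polarity)) {
    polarity <- if (walls_are_dark(y, step)) "dark" else "bright"
  }
  if (polarity == "dark") y <- 1 - y
  out <- tibble(position = as.numeric(position), intensity = y)
  class(out) <- c("oct_profile", class(out))
  attr(out, "step") <- step
  attr(out, "polarity") <- polarity
  out
}

# Polarity vote: smooth, then compare the total prominence of the two
# strongest maxima against the two strongest minima. Dark walls win when the
# inverted profile carries more feature prominence.
walls_are_dark <- function(y, step, sigma_steps = 2) {
  s <- gaussian_smooth(y, sigma_steps)
  top2 <- function(v) {
    pk <- find_local_maxima(v)
    if (length(pk) == 0L) return(0)
    pr <- sort(peak_prominence(v, pk), decreasing = TRUE)
    sum(head(pr, 2L))
  }
  top2(1 - s) > top2(s)
}

# Gaussian smoothing with edge replication; sigma in sampling steps.
gaussian_smooth <- function(y, sigma) {
  if (sigma <= 0) return(y)
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  ypad <- c(rep(y[1L], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1L):(half + length(y))]
}

# Indices of interior local maxima, plateau-aware (a flat-topped run counts
# once, at its middle sample). Runs touching the profile ends are excluded.
find_local_maxima <- function(y) {
  r <- rle(y)
  nruns <- length(r$values)
  if (nruns < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- 2:(nruns - 1L)
  is_peak <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  as.integer(floor((starts[j][is_peak] + ends[j][is_peak]) / 2))
}

# Topographic prominence of each peak: height above the higher of the two
# key saddles (minimum between the peak and the nearest higher ground on
# each side, or the profile end).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    higher_l <- which(y[seq_len(p - 1L)] > y[p])
    lo <- if (length(higher_l)) max(higher_l) else 1L
    left_min <- min(y[lo:p])
    right_idx <- (p + 1L):length(y)
    higher_r <- which(y[right_idx] > y[p])
    hi <- if (length(higher_r)) p + min(higher_r) else length(y)
    right_min <- min(y[p:hi])
    y[p] - max(left_min, right_min)
  }, numeric(1))
}

#' Detect the two vessel-wall features in a profile
#'
#' Finds the two most prominent local maxima of the profile, separated by an
#' interior minimum that marks the lumen. All quantities — extrema,
#' baselines, and the later half-maximum crossings — are read from one
#' lightly Gaussian-smoothed copy of the profile (default SD 2 sampling
#' steps, i.e. 0.5 um at the default 0.25 um step, roughly an order of
#' magnitude narrower than a typical point-spread width). A symmetric
#' unimodal kernel of this width leaves the half-maximum edge position of a
#' blurred step unchanged while suppressing the per-sample speckle that
#' would otherwise bias the nearest-crossing rule; `smooth_sigma = 0`
#' operates on the raw samples. Each wall gets per-side baselines: on its
#' outer side the median of the outer 10% tail of the profile, on its lumen
#' side the minimum intensity between the two walls.
#'
#' @param profile An `oct_profile` (see [extract_profile()], [make_profile()]).
#' @param smooth_sigma Measurement-smoothing SD in sampling steps (default
#'   2; 0 disables smoothing).
#' @param min_prominence Minimum normalized prominence for a wall candidate
#'   (default 0.05).
#' @return A two-row tibble (walls `"anterior"`, `"posterior"`, ordered by
#'   position) with columns `wall`, `extremum_position`, `extremum_intensity`,
#'   `left_baseline`, `right_baseline`.
#' @export
detect_wall_features <- function(profile, smooth_sigma = 2,
                                 min_prominence = 0.05) {
  stopifnot(inherits(profile, "oct_profile"))
  pos <- profile$position
  s <- gaussian_smooth(profile$intensity, smooth_sigma)
  peaks <- find_local_maxima(s)
  if (length(peaks) >= 1L) {
    prom <- peak_prominence(s, peaks)
    keep <- prom >= min_prominence
    peaks <- peaks[keep]
    prom <- prom[keep]
  }
  if (length(peaks) < 2L) {
    stop_octfwhm(
      "Fewer than two wall features above the prominence threshold.",
      "no_vessel")
  }
  sel <- pick_wall_pair(peaks, prom)
  idx <- order(peaks[sel])
  ia <- peaks[sel][idx[1L]]
  ip <- peaks[sel][idx[2L]]
  prom_a <- prom[sel][idx[1L]]
  prom_p <- prom[sel][idx[2L]]
  if (ia >= ip) {
    stop_octfwhm("Wall features collapse onto one extremum.", "no_vessel")
  }
  min_w <- max(2L, ceiling(2 * smooth_sigma))
  ext_a <- apex_fit(s, ia, cap_half_width(s, ia, 0.2 * prom_a, min_w))
  ext_p <- apex_fit(s, ip, cap_half_width(s, ip, 0.2 * prom_p, min_w))
  imin <- (ia:ip)[which.min(s[ia:ip])]
  depth <- 0.2 * (min(s[ia], s[ip]) - s[imin])
  lumen_min <- apex_fit(s, imin, cap_half_width(-s, imin, depth, min_w),
                        trough = TRUE)$value
  n <- length(s)
  tail_n <- max(1L, floor(0.1 * n))
  left_tail <- median(s[seq_len(tail_n)])
  right_tail <- median(s[(n - tail_n + 1L):n])
  step <- pos[2L] - pos[1L]
  feats <- tibble(
    wall = c("anterior", "posterior"),
    extremum_position = c(pos[ia] + ext_a$offset * step,
                          pos[ip] + ext_p$offset * step),
    extremum_intensity = c(ext_a$value, ext_p$value),
    left_baseline = c(left_tail, lumen_min),
    right_baseline = c(lumen_min, right_tail)
  )
  bad <- feats$extremum_intensity <=
    pmax(feats$left_baseline, feats$right_baseline)
  if (any(bad)) {
    stop_octfwhm("A wall extremum does not rise above its baselines.",
                 "no_vessel")
  }
  feats
}

# Half-width (in samples) of the contiguous "cap" of a peak: samples within
# `drop` of the peak value on both sides, symmetrized, clamped to
# [min_w, 40]. Fitting over the cap anchors the apex estimate to the feature
# shape instead of to the noise excursion that won the argmax, removing the
# selection bias of a pointwise maximum. Pass -s for troughs.
cap_half_width <- function(s, i, drop, min_w) {
  lvl <- s[i] - drop
  l <- 0L
  while (i - l - 1L >= 1L && s[i - l - 1L] >= lvl) l <- l + 1L
  r <- 0L
  while (i + r + 1L <= length(s) && s[i + r + 1L] >= lvl) r <- r + 1L
  max(min_w, min(l, r, 40L))
}

# Local quadratic fit around a sample extremum: averages noise over the
# window instead of taking the (upward-biased) pointwise maximum, and gives
# a sub-sample apex offset. Falls back to the sample value when the fit is
# not concave (convex for troughs) or the window is clipped.
apex_fit <- function(y, i, half_w, trough = FALSE) {
  lo <- i - half_w
  hi <- i + half_w
  if (lo < 1L || hi > length(y)) {
    return(list(value = y[i], offset = 0))
  }
  t <- seq(-half_w, half_w)
  yy <- y[lo:hi]
  fit <- stats::lm.fit(cbind(1, t, t^2), yy)$coefficients
  a <- fit[[3L]]
  concave_ok <- if (trough) a > 0 else a < 0
  if (!concave_ok) return(list(value = y[i], offset = 0))
  off <- -fit[[2L]] / (2 * a)
  if (abs(off) > half_w) return(list(value = y[i], offset = 0))
  list(value = fit[[1L]] - fit[[2L]]^2 / (4 * a), offset = off)
}

# Choose the two wall candidates: greatest prominence, ties (to within 1e-12)
# broken by the larger spatial separation.
pick_wall_pair <- function(peaks, prom) {
  ord <- order(prom, decreasing = TRUE)
  if (length(peaks) == 2L) return(ord)
  cut <- prom[ord[2L]] - 1e-12
  cand <- which(prom >= cut)
  if (length(cand) == 2L) return(cand)
  pairs <- utils::combn(cand, 2L)
  score <- prom[pairs[1L, ]] + prom[pairs[2L, ]]
  sep <- abs(peaks[pairs[1L, ]] - peaks[pairs[2L, ]])
  best <- order(-score, -sep)[1L]
  pairs[, best]
}

#' Half-maximum boundary crossings of one wall feature
#'
#' For each flank of the wall, the boundary is placed where the measurement
#' profile (smoothed as in [detect_wall_features()]) crosses
#' `baseline + (extremum - baseline) / 2`, at sub-pixel precision by linear
#' interpolation between the two bracketing samples. When a flank crosses
#' the threshold more than once, the crossing nearest the extremum is taken,
#' which prevents capture by a neighbouring vessel.
#'
#' @param profile An `oct_profile`.
#' @param feature One row of [detect_wall_features()] output (or a list with
#'   the same fields).
#' @inheritParams detect_wall_features
#' @return Named numeric `c(left = , right = )`, micrometre positions.
#' @export
half_max_crossings <- function(profile, feature, smooth_sigma = 2) {
  stopifnot(inherits(profile, "oct_profile"))
  if (is.data.frame(feature)) {
    if (nrow(feature) != 1L) {
      stop_octfwhm("`feature` must be a single wall feature row.",
                   "validation")
    }
    feature <- as.list(feature)
  }
  y <- gaussian_smooth(profile$intensity, smooth_sigma)
  pos <- profile$position
  ipk <- which.min(abs(pos - feature$extremum_position))
  peak_i <- feature$extremum_intensity
  if (peak_i <= max(feature$left_baseline, feature$right_baseline)) {
    stop_octfwhm("Extremum must lie strictly above both baselines.",
                 "validation")
  }
  # A candidate downcross must be sustained for `hold` samples (about 1 um
  # at the default step): transient noise dips narrower than the blur are
  # not vessel boundaries. On a noiseless monotone flank this is a no-op.
  hold <- max(1L, ceiling(2 * smooth_sigma))
  cross_side <- function(baseline, dir) {
    thr <- baseline + (peak_i - baseline) / 2
    i <- ipk
    repeat {
      j <- i + dir
      if (j < 1L || j > length(y)) {
        stop_octfwhm("Half-maximum level is never crossed on one flank.",
                     "boundary")
      }
      if ((y[i] >= thr && y[j] < thr) || (y[i] > thr && y[j] <= thr)) {
        run <- seq(j, by = dir, length.out = hold)
        run <- run[run >= 1L & run <= length(y)]
        if (all(y[run] <= thr)) {
          frac <- (y[i] - thr) / (y[i] - y[j])
          return(pos[i] + frac * (pos[j] - pos[i]))
        }
      }
      i <- j
    }
  }
  c(left = cross_side(feature$left_baseline, -1L),
    right = cross_side(feature$right_baseline, +1L))
}

#' Measure vessel outer and lumen diameters from a profile
#'
#' The full FWHM measurement: detect the anterior and posterior wall
#' features, locate the four half-maximum boundary points, and report
#' * outer diameter = posterior outer crossing − anterior outer crossing
#'   (RAOD for arteries, RVOD for veins),
#' * lumen diameter = posterior inner crossing − anterior inner crossing
#'   (RALD / RVLD),
#' * wall thickness = (outer − lumen) / 2 (AWT / VWT).
#'
#' @inheritParams detect_wall_features
#' @param kind `"artery"` or `"vein"`.
#' @return A one-row tibble of class `vessel_measurement` with columns
#'   `kind`, `outer_um`, `lumen_um`, `wall_um`, `n_repeats`; the four
#'   boundary positions are kept in the `boundaries` attribute.
#' @examples
#' sim <- make_profile(synth_vessel_spec(psf_sigma = 2, seed = 7))
#' measure_vessel(sim$profile, "artery")
#' @export
measure_vessel <- function(profile, kind = c("artery", "vein"),
                           smooth_sigma = 2, min_prominence = 0.05) {
  kind <- match.arg(kind)
  feats <- detect_wall_features(profile, smooth_sigma, min_prominence)
  ant <- half_max_crossings(profile, feats[1L, ], smooth_sigma)
  post <- half_max_crossings(profile, feats[2L, ], smooth_sigma)
  outer <- post[["right"]] - ant[["left"]]
  lumen <- post[["left"]] - ant[["right"]]
  if (lumen <= 0) {
    stop_octfwhm("Wall features overlap: lumen diameter is not positive.",
                 "overlap")
  }
  new_measurement(kind, outer, lumen,
                  boundaries = c(anterior_left = ant[["left"]],
                                 anterior_right = ant[["right"]],
                                 posterior_left = post[["left"]],
                                 posterior_right = post[["right"]]))
}

new_measurement <- function(kind, outer, lumen, n_repeats = 1L,
                            boundaries = NULL, repeats = NULL) {
  out <- tibble(kind = kind, outer_um = outer, lumen_um = lumen,
                wall_um = (outer - lumen) / 2, n_repeats = as.integer(n_repeats))
  class(out) <- c("vessel_measurement", class(out))
  attr(out, "boundaries") <- boundaries
  attr(out, "repeats") <- repeats
  out
}

#' Average repeated measurements of one vessel
#'
#' Each vessel is measured on repeated scans (three repeats in routine use)
#' and the diameters are averaged arithmetically; wall thickness is
#' recomputed from the averaged diameters so the identity
#' `wall = (outer - lumen) / 2` holds exactly for the output as well.
#'
#' @param measurements A `vessel_measurement` tibble (one row per repeat) or
#'   a list of one-row measurements, all of the same `kind`.
#' @return A one-row `vessel_measurement`; the per-repeat values are kept in
#'   the `repeats` attribute.
#' @export
average_repeats <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements)) {
    measurements <- dplyr::bind_rows(measurements)
  }
  if (!is.data.frame(measurements) || nrow(measurements) == 0L) {
    stop_octfwhm("`measurements` must contain at least one measurement.",
                 "input")
  }
  if (length(unique(measurements$kind)) != 1L) {
    stop_octfwhm("All repeats must be of the same vessel kind.", "validation")
  }
  new_measurement(
    kind = measurements$kind[1L],
    outer = mean(measurements$outer_um),
    lumen = mean(measurements$lumen_um),
    n_repeats = nrow(measurements),
    repeats = measurements[, c("outer_um", "lumen_um")]
  )
}
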