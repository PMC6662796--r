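# Independent oracles kept deliberately naive: direct loops and dense-grid
# searches, sharing no code with the package internals they check.

# Per-point bilinear interpolation by explicit double indexing.
oracle_bilinear <- function(px, x, y) {
  nr <- nrow(px)
  nc <- ncol(px)
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    xx <- min(max(x[k], 0), nc - 1)
    yy <- min(max(y[k], 0), nr - 1)
    x0 <- min(floor(xx), nc - 2)
    y0 <- min(floor(yy), nr - 2)
    fx <- xx - x0
    fy <- yy - y0
    out[k] <- (1 - fy) * ((1 - fx) * px[y0 + 1, x0 + 1] +
                            fx * px[y0 + 1, x0 + 2]) +
      fy * ((1 - fx) * px[y0 + 2, x0 + 1] + fx * px[y0 + 2, x0 + 2])
  }
  out
}

# Dense-grid brute-force threshold search on the profile's linear
# interpolant (grid = step / 1000), nearest crossing to the extremum.
oracle_crossing <- function(profile, feature, side) {
  pos <- profile$position
  y <- profile$intensity
  step <- pos[2] - pos[1]
  baseline <- if (side == "left") feature$left_baseline
              else feature$right_baseline
  thr <- baseline + (feature$extremum_intensity - baseline) / 2
  grid <- seq(pos[1], pos[length(pos)], by = step / 1000)
  yg <- approx(pos, y, xout = grid)$y
  ipk <- which.min(abs(grid - feature$extremum_position))
  dir <- if (side == "left") -1L else 1L
  i <- ipk
  repeat {
    j <- i + dir
    if (j < 1L || j > length(grid)) return(NA_real_)
    if (yg[i] >= thr && yg[j] < thr) {
      return(grid[i] + (yg[i] - thr) / (yg[i] - yg[j]) * (grid[j] - grid[i]))
    }
    i <- j
  }
}

# Mid-ranks by explicit counting: rank = (# smaller) + (1 + # equal) / 2.
oracle_midrank <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}

# Raw-data samples with exactly the requested mean and sample SD, by affine
# rescaling of an arbitrary draw.
exact_moment_sample <- function(n, mean, sd) {
  z <- rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# A random smooth unimodal (Gaussian-bump) profile plus its wall feature
# description, for crossing oracles.
random_unimodal_profile <- function() {
  x <- seq(0, 50, by = 0.25)
  b0 <- runif(1, 0, 0.2)
  a <- runif(1, 0.5, 0.9)
  cen <- runif(1, 15, 35)
  w <- runif(1, 2, 6)
  prof <- as_oct_profile(x, b0 + a * exp(-(x - cen)^2 / (2 * w^2)))
  ipk <- which.max(prof$intensity)
  feature <- list(
    extremum_position = prof$position[ipk],
    extremum_intensity = prof$intensity[ipk],
    left_baseline = min(prof$intensity[seq_len(ipk)]),
    right_baseline = min(prof$intensity[ipk:nrow(prof)])
  )
  list(profile = prof, feature = feature)
}

# Analytic moments of the generator's truncated joint draw: (outer, lumen)
# bivariate normal conditioned on lumen < outer. Standard truncated-normal
# algebra via the regression decomposition on the difference D = O - L.
oracle_truncated_moments <- function(mean_outer, sd_outer, mean_lumen,
                                     sd_lumen, rho) {
  md <- mean_outer - mean_lumen
  vd <- sd_outer^2 + sd_lumen^2 - 2 * rho * sd_outer * sd_lumen
  sdd <- sqrt(vd)
  a <- -md / sdd
  lam <- dnorm(a) / (1 - pnorm(a))
  ed <- md + sdd * lam
  vdt <- vd * (1 + a * lam - lam^2)
  b_o <- (sd_outer^2 - rho * sd_outer * sd_lumen) / vd
  b_l <- (rho * sd_outer * sd_lumen - sd_lumen^2) / vd
  list(
    mean_outer = mean_outer + b_o * (ed - md),
    sd_outer = sqrt(b_o^2 * vdt + sd_outer^2 - b_o^2 * vd),
    mean_lumen = mean_lumen + b_l * (ed - md),
    sd_lumen = sqrt(b_l^2 * vdt + sd_lumen^2 - b_l^2 * vd)
  )
}
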