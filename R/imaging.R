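#' Calibrated OCT B-scan image
#'
#' Container for a grayscale SD-OCT B-scan with explicit physical pixel
#' pitches. The pixel grid is a numeric matrix with rows along the axial
#' (depth) axis and columns along the lateral (transverse) axis. Physical
#' coordinates follow the convention that the centre of pixel `[1, 1]` is at
#' `(0, 0)` micrometres and pixel `[i, j]` is at
#' `x = (j - 1) * lateral_scale`, `y = (i - 1) * axial_scale`.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param axial_scale Micrometres per pixel along the depth (row) axis.
#' @param lateral_scale Micrometres per pixel along the transverse (column)
#'   axis.
#' @param bit_depth Integer bit depth of the source raster (informational).
#' @param source_id Opaque identifier carried through to measurement output.
#'
#' @return An object of class `oct_image`.
#' @examples
#' img <- oct_image(matrix(runif(64), 8), axial_scale = 4, lateral_scale = 11)
#' dim(img$pixels)
#' @export
oct_image <- function(pixels, axial_scale, lateral_scale, bit_depth = 8L,
                      source_id = "unknown") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_octfwhm("`pixels` must be a non-empty numeric matrix.", "validation")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop_octfwhm("Pixel intensities must be finite and non-negative.",
                 "validation")
  }
  check_number(axial_scale, "axial_scale", positive = TRUE)
  check_number(lateral_scale, "lateral_scale", positive = TRUE)
  structure(
    list(pixels = pixels, axial_scale = axial_scale,
         lateral_scale = lateral_scale, bit_depth = as.integer(bit_depth),
         source_id = as.character(source_id)),
    class = "oct_image"
  )
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf(
    "<oct_image> %d x %d px, %.3g x %.3g um/px (axial x lateral), %d-bit, id '%s'\n",
    nrow(x$pixels), ncol(x$pixels), x$axial_scale, x$lateral_scale,
    x$bit_depth, x$source_id))
  invisible(x)
}

# Bilinear interpolation at 0-based pixel coordinates (x = column, y = row).
# Coordinates are clamped to the grid so exact boundary positions evaluate to
# the boundary pixel value. Vectorized over x and y.
bilinear_sample <- function(pixels, x, y) {
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  x0 <- pmin(pmax(floor(x), 0), max(nc - 2L, 0L))
  y0 <- pmin(pmax(floor(y), 0), max(nr - 2L, 0L))
  fx <- pmin(pmax(x - x0, 0), 1)
  fy <- pmin(pmax(y - y0, 0), 1)
  x1 <- pmin(x0 + 1, nc - 1L)
  y1 <- pmin(y0 + 1, nr - 1L)
  v00 <- pixels[cbind(y0 + 1L, x0 + 1L)]
  v01 <- pixels[cbind(y0 + 1L, x1 + 1L)]
  v10 <- pixels[cbind(y1 + 1L, x0 + 1L)]
  v11 <- pixels[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

collapse_grayscale <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    # drop an alpha channel if present, collapse colour by channel mean
    use <- if (nch %in% c(2L, 4L)) seq_len(nch - 1L) else seq_len(nch)
    out <- arr[, , use[1L]]
    if (length(use) > 1L) {
      for (k in use[-1L]) out <- out + arr[, , k]
      out <- out / length(use)
    }
    return(out)
  }
  stop_octfwhm("Unsupported raster dimensionality.", "input")
}

# Minimal reader for uncompressed BMP (BITMAPINFOHEADER, 8-bit palette or
# 24/32-bit BGR), the screenshot format exported by the acquisition device.
# Returns intensities scaled to [0, 1]. No installed package reads BMP.
read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM") {
    stop_octfwhm(sprintf("'%s' is not a BMP file.", path), "input")
  }
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  data_offset <- u32(11)
  header_size <- u32(15)
  width <- u32(19)
  height_raw <- u32(23)
  top_down <- height_raw > 2^31
  height <- if (top_down) 2^32 - height_raw else height_raw
  bpp <- u16(29)
  compression <- u32(31)
  if (compression != 0 || !(bpp %in% c(8L, 24L, 32L))) {
    stop_octfwhm("Only uncompressed 8/24/32-bit BMP is supported.", "input")
  }
  palette <- NULL
  if (bpp == 8L) {
    ncolors <- u32(47)
    if (ncolors == 0) ncolors <- 256
    pal_raw <- raw[(14 + header_size + 1):(14 + header_size + 4 * ncolors)]
    pal <- matrix(as.integer(pal_raw), nrow = 4)  # B, G, R, reserved
    palette <- colMeans(pal[1:3, , drop = FALSE]) / 255
  }
  bytes_pp <- bpp %/% 8L
  stride <- ((width * bytes_pp + 3) %/% 4) * 4
  out <- matrix(0, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    row0 <- data_offset + (r - 1) * stride
    idx <- row0 + seq_len(width * bytes_pp)
    vals <- as.integer(raw[idx])
    px <- if (bpp == 8L) {
      palette[vals + 1L]
    } else {
      m <- matrix(vals, nrow = bytes_pp)
      colMeans(m[1:3, , drop = FALSE]) / 255  # average B, G, R
    }
    dest <- if (top_down) r else height - r + 1L
    out[dest, ] <- px
  }
  out
}

#' Load a B-scan image with physical calibration
#'
#' Reads a PNG, TIFF or uncompressed BMP raster, collapses colour images to
#' grayscale by channel mean, and attaches the stated micrometre-per-pixel
#' scales. Pixel pitches are never guessed from file metadata: the device
#' calibration must be supplied (directly or via [read_scan_config()]).
#' Intensities are returned in `[0, 1]`; 16-bit data keeps its full
#' precision.
#'
#' @param path Path to a PNG/TIFF/BMP file.
#' @inheritParams oct_image
#' @return An [oct_image()].
#' @export
load_oct_image <- function(path, axial_scale, lateral_scale) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_octfwhm(sprintf("Image file '%s' does not exist.", path), "input")
  }
  check_number(axial_scale, "axial_scale", positive = TRUE)
  check_number(lateral_scale, "lateral_scale", positive = TRUE)
  ext <- tolower(tools::file_ext(path))
  bit_depth <- 8L
  arr <- switch(
    ext,
    png = {
      a <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop_octfwhm(
                      sprintf("Cannot decode PNG '%s': %s", path,
                              conditionMessage(e)), "input"))
      info <- attr(a, "info")
      if (!is.null(info$bit.depth)) bit_depth <- as.integer(info$bit.depth)
      a
    },
    tif = ,
    tiff = tryCatch({
      a <- tiff::readTIFF(path)
      # 16-bit TIFF decodes on a 1/65535 lattice; detect off-8-bit values
      if (any(abs(a * 255 - round(a * 255)) > 1e-9)) bit_depth <- 16L
      a
    }, error = function(e) stop_octfwhm(
      sprintf("Cannot decode TIFF '%s': %s", path, conditionMessage(e)),
      "input")),
    bmp = read_bmp_gray(path),
    stop_octfwhm(sprintf("Unsupported image format '.%s'.", ext), "input")
  )
  oct_image(collapse_grayscale(arr), axial_scale, lateral_scale,
            bit_depth = bit_depth, source_id = basename(path))
}

#' Write an OCT image to disk
#'
#' 16-bit output uses TIFF (lossless for the 65536-level lattice); 8-bit
#' output may use PNG or TIFF. Intensities must lie in `[0, 1]` and are
#' quantized to the target bit depth; the quantized image is returned
#' invisibly so callers can assert exact read-back.
#'
#' @param image An [oct_image()].
#' @param path Output path; extension selects the container (.png/.tif).
#' @param bit_depth 8 or 16.
#' @return Invisibly, the quantized [oct_image()] actually written.
#' @export
write_oct_image <- function(image, path, bit_depth = 16L) {
  stopifnot(inherits(image, "oct_image"))
  if (!bit_depth %in% c(8L, 16L)) {
    stop_octfwhm("`bit_depth` must be 8 or 16.", "validation")
  }
  px <- image$pixels
  if (max(px) > 1) px <- px / max(px)
  levels <- 2^bit_depth - 1
  q <- round(px * levels) / levels
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8L) {
      stop_octfwhm("PNG output supports 8-bit only; use .tif for 16-bit.",
                   "validation")
    }
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = bit_depth)
  } else {
    stop_octfwhm(sprintf("Unsupported output format '.%s'.", ext), "input")
  }
  invisible(oct_image(q, image$axial_scale, image$lateral_scale,
                      bit_depth = bit_depth, source_id = basename(path)))
}

#' Resample a B-scan to an isotropic micrometre grid
#'
#' Bilinear resampling to equal axial and lateral pitches, mirroring the
#' 1:1 um display normalization used during acquisition review. The physical
#' extent of the image is preserved to within one pixel per axis.
#'
#' @param image An [oct_image()].
#' @param target_scale Output pitch in micrometres per pixel (both axes).
#'   Defaults to 1 um/px.
#' @return An isotropic [oct_image()].
#' @export
resample_isotropic <- function(image, target_scale = 1) {
  stopifnot(inherits(image, "oct_image"))
  check_number(target_scale, "target_scale", positive = TRUE)
  if (image$axial_scale == target_scale && image$lateral_scale == target_scale) {
    return(image)
  }
  if (target_scale > 4 * min(image$axial_scale, image$lateral_scale)) {
    warn(paste("`target_scale` is more than 4x coarser than the input pitch;",
               "fine structure will be lost."),
         class = "octfwhm_warning_downsample")
  }
  px <- image$pixels
  extent_x <- (ncol(px) - 1) * image$lateral_scale
  extent_y <- (nrow(px) - 1) * image$axial_scale
  nc2 <- floor(extent_x / target_scale + 1e-9) + 1L
  nr2 <- floor(extent_y / target_scale + 1e-9) + 1L
  xs <- (seq_len(nc2) - 1) * target_scale / image$lateral_scale
  ys <- (seq_len(nr2) - 1) * target_scale / image$axial_scale
  vals <- bilinear_sample(px,
                          x = rep(xs, each = nr2),
                          y = rep(ys, times = nc2))
  oct_image(matrix(vals, nrow = nr2, ncol = nc2),
            axial_scale = target_scale, lateral_scale = target_scale,
            bit_depth = image$bit_depth, source_id = image$source_id)
}

#' Optic-disc geometry and the zone-B annulus
#'
#' Zone B is the annular region around the optic disc classically used for
#' vessel caliber measurement, bounded here by two concentric circles at one
#' and one-and-a-half disc diameters. The radii are measured from the disc
#' centre by default; because the literature is ambiguous about whether such
#' circles are referenced to the disc centre or the disc margin, both
#' conventions are supported and the choice is recorded in the object.
#'
#' @param disc_center Numeric `(x, y)` of the disc centre, micrometres.
#' @param disc_diameter Disc diameter in micrometres.
#' @param inner_factor,outer_factor Multiples of the disc diameter giving the
#'   annulus radii (defaults 1.0 and 1.5).
#' @param reference `"center"` (radii from disc centre) or `"margin"` (radii
#'   from the disc margin, i.e. the disc radius is added).
#' @param inner_radius,outer_radius Explicit radii in micrometres; override
#'   the factor-based defaults when given.
#' @return An object of class `disc_geometry`.
#' @examples
#' g <- disc_geometry(c(0, 0), disc_diameter = 1500)
#' zone_b_contains(g, c(1600, 0))
#' @export
disc_geometry <- function(disc_center, disc_diameter,
                          inner_factor = 1.0, outer_factor = 1.5,
                          reference = c("center", "margin"),
                          inner_radius = NULL, outer_radius = NULL) {
  reference <- match.arg(reference)
  if (!is.numeric(disc_center) || length(disc_center) != 2L ||
      anyNA(disc_center)) {
    stop_octfwhm("`disc_center` must be a numeric (x, y) pair.", "validation")
  }
  check_number(disc_diameter, "disc_diameter", positive = TRUE)
  offset <- if (reference == "margin") disc_diameter / 2 else 0
  if (is.null(inner_radius)) inner_radius <- inner_factor * disc_diameter + offset
  if (is.null(outer_radius)) outer_radius <- outer_factor * disc_diameter + offset
  check_number(inner_radius, "inner_radius", positive = TRUE)
  check_number(outer_radius, "outer_radius", positive = TRUE)
  if (inner_radius >= outer_radius) {
    stop_octfwhm("`inner_radius` must be smaller than `outer_radius`.",
                 "validation")
  }
  structure(
    list(disc_center = as.numeric(disc_center),
         disc_diameter = disc_diameter,
         zone_b_inner_radius = inner_radius,
         zone_b_outer_radius = outer_radius,
         reference = reference),
    class = "disc_geometry"
  )
}

#' @rdname disc_geometry
#' @param geometry A `disc_geometry` object.
#' @param points A length-2 `(x, y)` vector, an n-by-2 matrix, or a data
#'   frame with columns `x` and `y` (micrometres).
#' @return For `zone_b_contains()`, a logical vector: `TRUE` where the point
#'   lies inside the closed zone-B annulus.
#' @export
zone_b_contains <- function(geometry, points) {
  stopifnot(inherits(geometry, "disc_geometry"))
  if (is.data.frame(points)) points <- cbind(points$x, points$y)
  if (is.numeric(points) && is.null(dim(points))) {
    points <- matrix(points, ncol = 2L, byrow = TRUE)
  }
  d <- sqrt((points[, 1] - geometry$disc_center[1])^2 +
              (points[, 2] - geometry$disc_center[2])^2)
  d >= geometry$zone_b_inner_radius & d <= geometry$zone_b_outer_radius
}

#' Define a line scan across a vessel
#'
#' A straight sampling segment in physical (micrometre) coordinates, placed
#' manually as perpendicular as possible to the vessel axis. The default
#' 0.25 um step gives four-fold sub-pixel sampling on a 1 um/px isotropic
#' image.
#'
#' @param p0,p1 Numeric `(x, y)` endpoints in micrometres.
#' @param step Sampling interval along the line, micrometres.
#' @return An object of class `scan_line`.
#' @export
scan_line <- function(p0, p1, step = 0.25) {
  if (!is.numeric(p0) || length(p0) != 2L || !is.numeric(p1) ||
      length(p1) != 2L || anyNA(c(p0, p1))) {
    stop_octfwhm("`p0` and `p1` must be numeric (x, y) pairs.", "validation")
  }
  if (all(p0 == p1)) {
    stop_octfwhm("Scan line endpoints must differ.", "validation")
  }
  check_number(step, "step", positive = TRUE)
  structure(list(p0 = as.numeric(p0), p1 = as.numeric(p1), step = step),
            class = "scan_line")
}

#' Read a sidecar calibration config
#'
#' YAML or JSON sidecar with fields `axial_scale_um`, `lateral_scale_um` and
#' optionally `disc_center` and `disc_diameter_um`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A named list with the calibration fields.
#' @export
read_scan_config <- function(path) {
  if (!file.exists(path)) {
    stop_octfwhm(sprintf("Config file '%s' does not exist.", path), "input")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_octfwhm("Config must be YAML or JSON.", "input")
  }
  for (f in c("axial_scale_um", "lateral_scale_um")) {
    if (is.null(cfg[[f]])) {
      stop_octfwhm(sprintf("Config is missing required field '%s'.", f),
                   "validation")
    }
    check_number(cfg[[f]], f, positive = TRUE)
  }
  cfg
}
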