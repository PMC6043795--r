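# Multiband plot rasters: the band-stack container, calibration panel
# scenes, DN distortion (inverse empirical line), and the textured synthetic
# image generator.

MCA6_CENTERS <- c(490, 550, 680, 720, 800, 900)
TEXTURE_BANDS <- c(490, 550, 680, 720, 800)

#' Construct a multiband raster stack
#'
#' A band stack is a 3-D array of pixels (rows x cols x bands) with band
#' centre wavelengths, a value kind (`"DN"` or `"reflectance"`), and a
#' simple affine georeference: pixel `(r, c)` has centre coordinates
#' `x = x0 + (c - 0.5) * px`, `y = y0 + (r - 0.5) * px` (row-down frame).
#' Polygons used for zonal statistics live in the same frame.
#'
#' @param values numeric array `[rows, cols, bands]`.
#' @param centers band centre wavelengths (nm), strictly increasing.
#' @param kind `"DN"` or `"reflectance"`.
#' @param transform list with origin `x0`, `y0` and square pixel size `px`.
#' @return a `band_stack`.
#' @export
band_stack <- function(values, centers, kind = c("reflectance", "DN"),
                       transform = list(x0 = 0, y0 = 0, px = 1)) {
  kind <- match.arg(kind)
  if (length(dim(values)) != 3L)
    stop_pnc("pnc_invalid_config", "values must be a rows x cols x bands array")
  if (dim(values)[3] != length(centers))
    stop_pnc("pnc_invalid_config", "band count does not match centers")
  if (length(centers) > 1 && any(diff(centers) <= 0))
    stop_pnc("pnc_invalid_config", "band centers must be strictly increasing")
  structure(list(values = values, centers = centers, kind = kind,
                 transform = transform),
            class = "band_stack")
}

#' Extract one band of a stack as a matrix
#' @param stack a `band_stack`.
#' @param center_nm band centre to extract (must match exactly).
#' @return numeric matrix.
#' @export
stack_band <- function(stack, center_nm) {
  i <- match(center_nm, stack$centers)
  if (is.na(i))
    stop_pnc("pnc_missing_band", "stack has no band at %g nm", center_nm)
  d <- dim(stack$values)
  matrix(stack$values[, , i], d[1], d[2])
}

#' Per-band global means of a stack
#' @param stack a `band_stack`.
#' @return named numeric vector keyed by band centre.
#' @export
band_means <- function(stack) {
  m <- apply(stack$values, 3, mean)
  names(m) <- as.character(stack$centers)
  m
}

#' Construct a calibration panel set
#'
#' Reference canvases of known, spectrally flat reflectance used for the
#' empirical line fit. Reflectances must be strictly increasing across
#' panels and lie in (0, 1).
#'
#' @param reflectance numeric vector (one flat value per panel) or matrix
#'   `[panels x bands]`.
#' @param polygons list of xy vertex matrices, one per panel, in the frame
#'   of the calibration stack.
#' @param centers band centres (nm) for the columns when `reflectance` is a
#'   matrix (or to replicate a flat vector over).
#' @return a `panel_set`.
#' @export
panel_set <- function(reflectance, polygons, centers = MCA6_CENTERS) {
  if (is.vector(reflectance))
    reflectance <- matrix(reflectance, nrow = length(reflectance),
                          ncol = length(centers))
  if (any(reflectance <= 0) || any(reflectance >= 1))
    stop_pnc("pnc_invalid_config", "panel reflectances must lie in (0, 1)")
  if (any(apply(reflectance, 2, function(v) any(diff(v) <= 0))))
    stop_pnc("pnc_invalid_config",
             "panel reflectances must increase strictly across panels")
  if (length(polygons) != nrow(reflectance))
    stop_pnc("pnc_invalid_config", "one polygon per panel required")
  colnames(reflectance) <- as.character(centers)
  structure(list(reflectance = reflectance, polygons = polygons,
                 centers = centers),
            class = "panel_set")
}

#' Synthetic calibration panel scene
#'
#' Lays `length(values)` flat panels as squares in a row on a soil
#' background and returns both the reflectance stack and the matching
#' `panel_set` (polygons are buffered one pixel inside each square).
#'
#' @param values panel reflectances, strictly increasing (default six
#'   canvases from 0.03 to 0.60).
#' @param panel_px side of each panel in pixels.
#' @param gap gap between/around panels in pixels.
#' @param centers band centres of the scene.
#' @return list with elements `stack` (reflectance `band_stack`) and
#'   `panels` (a `panel_set`).
#' @export
panel_scene <- function(values = c(0.03, 0.12, 0.24, 0.36, 0.48, 0.60),
                        panel_px = 10, gap = 4, centers = MCA6_CENTERS) {
  np <- length(values)
  nr <- panel_px + 2 * gap
  nc <- np * panel_px + (np + 1) * gap
  soil <- soil_endmember(centers)
  vals <- array(rep(soil, each = nr * nc), dim = c(nr, nc, length(centers)))
  polys <- vector("list", np)
  for (p in seq_len(np)) {
    c0 <- gap + (p - 1) * (panel_px + gap)  # left edge, x units = pixels
    vals[(gap + 1):(gap + panel_px), (c0 + 1):(c0 + panel_px), ] <- values[p]
    polys[[p]] <- rect_polygon(c0 + 1, gap + 1, c0 + panel_px - 1,
                               gap + panel_px - 1)
  }
  list(stack = band_stack(vals, centers, "reflectance"),
       panels = panel_set(values, polys, centers))
}

#' Axis-aligned rectangle polygon
#' @param x0,y0,x1,y1 corner coordinates.
#' @return 5-row xy vertex matrix (closed ring).
#' @export
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
}

#' DN distortion (inverse empirical line)
#'
#' The synthetic sensor records digital numbers related to reflectance by a
#' per-band affine law `reflectance = gain * DN + offset`; this object holds
#' the true per-band parameters used to distort reflectance into DN.
#'
#' @param gains,offsets numeric vectors, one value per band.
#' @param centers band centres the parameters refer to.
#' @return a `dn_distortion`.
#' @export
dn_distortion <- function(gains, offsets, centers = MCA6_CENTERS) {
  stopifnot(length(gains) == length(centers),
            length(offsets) == length(centers))
  if (any(!is.finite(gains)) || any(gains == 0))
    stop_pnc("pnc_invalid_config", "gains must be finite and nonzero")
  structure(list(gains = gains, offsets = offsets, centers = centers),
            class = "dn_distortion")
}

#' Default DN distortion for the synthetic 10-bit sensor
#' @param seed integer seed for small per-band parameter jitter.
#' @return a `dn_distortion`.
#' @export
default_dn_distortion <- function(seed = 1L) {
  nb <- length(MCA6_CENTERS)
  with_seed(derive_seed(seed, "dn"), {
    gains <- 1 / stats::runif(nb, 900, 1200)   # ~10-bit dynamic range
    offsets <- stats::runif(nb, -0.03, 0.01)
    dn_distortion(gains, offsets)
  })
}

#' Distort a reflectance stack to DN
#' @param stack reflectance `band_stack`.
#' @param dn a [dn_distortion()].
#' @return DN `band_stack`.
#' @export
to_dn <- function(stack, dn) {
  stopifnot(inherits(dn, "dn_distortion"), stack$kind == "reflectance")
  if (!identical(as.numeric(stack$centers), as.numeric(dn$centers)))
    stop_pnc("pnc_band_mismatch", "distortion bands do not match stack bands")
  v <- stack$values
  for (b in seq_along(dn$centers))
    v[, , b] <- (v[, , b] - dn$offsets[b]) / dn$gains[b]
  band_stack(v, stack$centers, "DN", stack$transform)
}

# Standardized correlated random field: Gaussian-smoothed white noise with
# kernel length `kernel_sd` pixels, rescaled to mean 0 / sd 1. kernel_sd = 0
# returns standardized white noise. Separable smoothing is applied as two
# banded matrix products with reflected edges.
gauss_field <- function(nr, nc, kernel_sd = 2) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (kernel_sd > 0) {
    Kr <- smooth_matrix(nr, kernel_sd)
    Kc <- if (nc == nr) Kr else smooth_matrix(nc, kernel_sd)
    z <- Kr %*% z %*% t(Kc)
  }
  s <- stats::sd(as.numeric(z))
  if (s > 0) z <- (z - mean(z)) / s
  z
}

# n x n Gaussian smoothing operator with reflected boundaries.
smooth_matrix <- function(n, kernel_sd) {
  half <- max(1L, ceiling(3 * kernel_sd))
  k <- stats::dnorm(-half:half, sd = kernel_sd)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -half:half) {
    j <- i + o
    j <- ifelse(j < 1L, 2L - j, ifelse(j > n, 2L * n - j, j))
    K[cbind(i, j)] <- K[cbind(i, j)] + k[o + half + 1L]
  }
  K
}

#' Image-generator configuration
#'
#' @param size raster side in pixels per plot (>= 32 so 3x3 texture windows
#'   have ample interior support).
#' @param kernel_sd Gaussian kernel length (pixels) of the correlated field.
#' @param illum_sd log-SD of the per-plot multiplicative illumination
#'   jitter common to all bands.
#' @param rel_sd base relative local SD of each band's field, scaled by the
#'   plot heterogeneity state.
#' @param tex_pnc_gain strength of the planted texture-variance link: the
#'   720 nm field's relative SD rises with PNC while the 800 nm field's
#'   falls, so variance-type texture contrasts at 720/800 carry PNC signal.
#' @param pixel_noise_sd additive per-pixel sensor noise (reflectance units).
#' @return an `img_config` list.
#' @export
img_config <- function(size = 48, kernel_sd = 2, illum_sd = 0.03,
                       rel_sd = 0.18, tex_pnc_gain = 0.6,
                       pixel_noise_sd = 0.003) {
  if (size < 32)
    stop_pnc("pnc_invalid_config",
             "plot rasters must be at least 32 x 32 pixels")
  structure(as.list(environment()), class = "img_config")
}

#' Generate a textured multiband plot raster
#'
#' Six bands at the camera centres (490/550/680/720/800/900 nm). Each
#' band's per-pixel values are `mean * illum * (1 + sd_rel * Z)` plus pixel
#' noise, where `mean` is the plot spectrum sampled at the band centre, `Z`
#' a correlated random field, and `illum` a per-plot illumination factor.
#' The relative field SD scales with the plot's heterogeneity state (denser
#' stands are smoother) and, at 720 and 800 nm, moves with PNC in opposite
#' directions — the construction that makes red-edge/NIR texture contrasts
#' recoverable predictors of PNC. With a `dn_distortion` the stack is
#' returned in DN via the inverse empirical line.
#'
#' @param truth_row one row of [generate_plot_truth()] output.
#' @param spectrum the plot's `spectrum` (its band-centre values set the
#'   per-band field means).
#' @param config an [img_config()].
#' @param dn optional [dn_distortion()]; when supplied the result is DN.
#' @param seed integer seed.
#' @return a `band_stack` with attribute `"illum"` (the drawn illumination
#'   factor).
#' @export
generate_ms_image <- function(truth_row, spectrum, config = img_config(),
                              dn = NULL, seed = 1L) {
  stopifnot(inherits(config, "img_config"))
  n <- config$size
  centers <- MCA6_CENTERS
  means <- sample_band(spectrum, centers)
  pnc_scaled <- clip01((truth_row$PNC_true - 0.8) / 2.5)
  with_seed(derive_seed(seed, "image", truth_row$sample_id %||% "plot"), {
    illum <- exp(stats::rnorm(1, 0, config$illum_sd))
    vals <- array(0, dim = c(n, n, length(centers)))
    for (b in seq_along(centers)) {
      gain <- switch(as.character(centers[b]),
                     `720` = 1 + config$tex_pnc_gain * pnc_scaled,
                     `800` = 1 - 0.5 * config$tex_pnc_gain * pnc_scaled,
                     1)
      sd_rel <- config$rel_sd * truth_row$het * gain
      z <- if (sd_rel > 0) gauss_field(n, n, config$kernel_sd) else 0
      band <- means[b] * illum * (1 + sd_rel * z)
      if (config$pixel_noise_sd > 0)
        band <- band + stats::rnorm(n * n, 0, config$pixel_noise_sd)
      vals[, , b] <- clip01(band, 1e-4, 0.9999)
    }
    out <- band_stack(vals, centers, "reflectance")
    if (!is.null(dn)) out <- to_dn(out, dn)
    attr(out, "illum") <- illum
    out
  })
}

#' Plot and sampling-exclusion polygons for a square plot raster
#'
#' The plot polygon is the raster inset by `margin` pixels; the exclusion is
#' the destructive-sampling corner (a square of side `sampling_frac * size`)
#' removed before zonal statistics — plot reflectance is averaged over the
#' non-sampling area only.
#'
#' @param size raster side (pixels).
#' @param margin inset from the raster edge (pixels).
#' @param sampling_frac side of the sampling corner as a fraction of `size`.
#' @return list with `plot` and `exclusion` xy polygon matrices.
#' @export
plot_polygons <- function(size, margin = 2, sampling_frac = 0.3) {
  s <- round(sampling_frac * size)
  list(plot = rect_polygon(margin, margin, size - margin, size - margin),
       exclusion = rect_polygon(margin, margin, margin + s, margin + s))
}
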