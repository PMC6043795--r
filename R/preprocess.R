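# Radiometric preprocessing: empirical line calibration, plot-level zonal
# reflectance, and sensor geometry.

# Logical mask of pixels whose centres fall inside `polygon` (minus
# `exclusion` if given). Pixel-centre containment, evaluated in the stack's
# coordinate frame.
pixel_mask <- function(stack, polygon, exclusion = NULL) {
  d <- dim(stack$values)
  tr <- stack$transform
  xs <- tr$x0 + (seq_len(d[2]) - 0.5) * tr$px
  ys <- tr$y0 + (seq_len(d[1]) - 0.5) * tr$px
  pts <- cbind(rep(xs, each = d[1]), rep(ys, times = d[2]))
  inside <- mgcv::in.out(as.matrix(polygon), pts)
  if (!is.null(exclusion))
    inside <- inside & !mgcv::in.out(as.matrix(exclusion), pts)
  matrix(inside, d[1], d[2])
}

#' Fit the empirical line model from calibration panels
#'
#' Per band, ordinary least squares of the panels' known reflectance on
#' their mean DN: `reflectance = gain * DN + offset`. Needs at least two
#' panels with distinct DN means.
#'
#' @param stack DN `band_stack` containing the panels.
#' @param panels a [panel_set()] whose polygons lie inside the stack.
#' @return an `empirical_line` model: data.frame per band with `band_nm`,
#'   `gain`, `offset`, `r_squared`, `n_panels`.
#' @export
fit_empirical_line <- function(stack, panels) {
  stopifnot(inherits(panels, "panel_set"))
  if (stack$kind != "DN")
    stop_pnc("pnc_invalid_config", "empirical line is fitted on DN imagery")
  np <- nrow(panels$reflectance)
  if (np < 2)
    stop_pnc("pnc_insufficient_calibration",
             "at least 2 calibration panels are required (got %d)", np)
  masks <- lapply(panels$polygons, function(p) pixel_mask(stack, p))
  if (any(vapply(masks, sum, integer(1)) == 0L))
    stop_pnc("pnc_insufficient_calibration",
             "a panel polygon covers no pixel centres")
  fits <- lapply(seq_along(stack$centers), function(b) {
    band <- stack$values[, , b]
    dn <- vapply(masks, function(m) mean(band[m]), numeric(1))
    rho <- panels$reflectance[, b]
    if (stats::var(dn) == 0)
      stop_pnc("pnc_degenerate_fit",
               "zero DN variance across panels at %g nm", stack$centers[b])
    fit <- stats::lm(rho ~ dn)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((rho - mean(rho))^2)
    data.frame(band_nm = stack$centers[b],
               gain = unname(stats::coef(fit)[2]),
               offset = unname(stats::coef(fit)[1]),
               r_squared = r2,
               n_panels = np)
  })
  structure(do.call(rbind, fits), class = c("empirical_line", "data.frame"))
}

#' Apply an empirical line model to a DN stack
#'
#' Per-pixel affine transform to reflectance, clipped to `[0, 1]`. The count
#' of clipped pixels is recorded in the `"n_clipped"` attribute of the
#' result.
#'
#' @param stack DN `band_stack`.
#' @param model an `empirical_line` fit covering all bands of the stack.
#' @return reflectance `band_stack` with attribute `n_clipped`.
#' @export
apply_empirical_line <- function(stack, model) {
  stopifnot(inherits(model, "empirical_line"))
  if (!all(stack$centers %in% model$band_nm))
    stop_pnc("pnc_band_mismatch",
             "model does not cover all bands of the stack")
  v <- stack$values
  n_clipped <- 0L
  for (b in seq_along(stack$centers)) {
    row <- model[model$band_nm == stack$centers[b], ]
    rho <- row$gain * v[, , b] + row$offset
    n_clipped <- n_clipped + sum(rho < 0 | rho > 1)
    v[, , b] <- clip01(rho)
  }
  out <- band_stack(v, stack$centers, "reflectance", stack$transform)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Plot-mean reflectance over the non-sampling area
#'
#' Arithmetic mean, per band, over pixels whose centres fall inside the plot
#' polygon and outside the exclusion polygon (the destructive-sampling
#' area).
#'
#' @param stack reflectance `band_stack`.
#' @param plot_polygon xy vertex matrix.
#' @param exclusion optional xy vertex matrix removed from the plot area.
#' @return named numeric vector, one mean per band (names are band centres).
#' @export
plot_mean_reflectance <- function(stack, plot_polygon, exclusion = NULL) {
  m <- pixel_mask(stack, plot_polygon, exclusion)
  if (!any(m))
    stop_pnc("pnc_empty_region",
             "no pixel centres remain inside the plot polygon")
  out <- apply(stack$values, 3, function(band) mean(band[m]))
  names(out) <- as.character(stack$centers)
  out
}

#' Camera footprint and ground sampling distance
#'
#' For a camera with rectangular field of view flown at nadir:
#' `footprint = 2 * altitude * tan(fov / 2)` per axis and
#' `gsd = footprint_x / pixels_x`. The six-band camera used here (38.26 x
#' 30.97 degree FOV, 1280 x 1024 pixels) gives a 69 x 55 m footprint and
#' 0.054 m GSD at 100 m above ground.
#'
#' @param fov_deg_x,fov_deg_y angular field of view (degrees), in (0, 180).
#' @param altitude_m flight height above ground (m), > 0.
#' @param pixels_x across-track pixel count.
#' @return named vector `footprint_x_m`, `footprint_y_m`, `gsd_m`.
#' @export
sensor_geometry <- function(fov_deg_x = 38.26, fov_deg_y = 30.97,
                            altitude_m = 100, pixels_x = 1280) {
  if (altitude_m <= 0)
    stop_pnc("pnc_invalid_config", "altitude must be > 0")
  if (any(c(fov_deg_x, fov_deg_y) <= 0) || any(c(fov_deg_x, fov_deg_y) >= 180))
    stop_pnc("pnc_invalid_config", "FOV must lie in (0, 180) degrees")
  fx <- 2 * altitude_m * tan(fov_deg_x * pi / 360)
  fy <- 2 * altitude_m * tan(fov_deg_y * pi / 360)
  c(footprint_x_m = fx, footprint_y_m = fy, gsd_m = fx / pixels_x)
}
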