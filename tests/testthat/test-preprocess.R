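make_panel_stack <- function(dn_values, n = 20) {
  # two or more flat panels side by side in a DN stack, one band per centre
  np <- length(dn_values)
  w <- n %/% np
  v <- array(0, dim = c(n, n, 6))
  polys <- vector("list", np)
  for (p in seq_len(np)) {
    cols <- ((p - 1) * w + 1):(p * w)
    v[, cols, ] <- dn_values[p]
    polys[[p]] <- rect_polygon((p - 1) * w, 0, p * w, n)
  }
  list(stack = band_stack(v, c(490, 550, 680, 720, 800, 900), "DN"),
       polys = polys)
}

test_that("two-point empirical line reproduces the hand-fitted gain/offset", {
  sc <- make_panel_stack(c(100, 200))
  panels <- panel_set(c(0.1, 0.3), sc$polys)
  elm <- fit_empirical_line(sc$stack, panels)
  expect_equal(elm$gain, rep(0.002, 6), tolerance = 1e-12)
  expect_equal(elm$offset, rep(-0.1, 6), tolerance = 1e-12)
  # applying the fit: DN 150 -> 0.002 * 150 - 0.1 = 0.2
  dn150 <- band_stack(array(150, dim = c(4, 4, 6)),
                      c(490, 550, 680, 720, 800, 900), "DN")
  out <- apply_empirical_line(dn150, elm)
  expect_equal(unname(band_means(out)), rep(0.2, 6))
})

test_that("identity panels give gain 1, offset 0; perfect lines give R2 = 1", {
  sc <- make_panel_stack(c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85), n = 24)
  panels <- panel_set(c(0.1, 0.25, 0.4, 0.55, 0.7, 0.85), sc$polys)
  elm <- fit_empirical_line(sc$stack, panels)
  expect_equal(elm$gain, rep(1, 6), tolerance = 1e-10)
  expect_equal(elm$offset, rep(0, 6), tolerance = 1e-10)
  expect_equal(elm$r_squared, rep(1, 6), tolerance = 1e-10)
  out <- apply_empirical_line(sc$stack, elm)
  expect_equal(out$values, sc$stack$values, tolerance = 1e-12)
})

test_that("calibration failure modes raise classed errors", {
  sc <- make_panel_stack(c(100, 200))
  expect_error(fit_empirical_line(sc$stack,
                                  panel_set(0.3, sc$polys[1])),
               class = "pnc_insufficient_calibration")
  flat <- make_panel_stack(c(100, 100))
  expect_error(fit_empirical_line(flat$stack,
                                  panel_set(c(0.1, 0.3), flat$polys)),
               class = "pnc_degenerate_fit")
  # reflectance input is not calibratable
  refl <- make_const_stack()
  expect_error(fit_empirical_line(refl, panel_set(c(0.1, 0.3), sc$polys)),
               class = "pnc_invalid_config")
})

test_that("clipping is applied and counted", {
  elm <- structure(data.frame(band_nm = c(490, 550, 680, 720, 800, 900),
                              gain = 1, offset = 0, r_squared = 1,
                              n_panels = 2),
                   class = c("empirical_line", "data.frame"))
  v <- array(0.5, dim = c(3, 3, 6))
  v[1, 1, 1] <- -0.05   # implies rho < 0 -> clipped to 0
  v[2, 2, 2] <- 1.40    # clipped to 1
  out <- apply_empirical_line(band_stack(v, elm$band_nm, "DN"), elm)
  expect_equal(attr(out, "n_clipped"), 2L)
  expect_equal(stack_band(out, 490)[1, 1], 0)
  expect_equal(stack_band(out, 550)[2, 2], 1)
})

test_that("plot means honour polygons, exclusions and linearity", {
  n <- 10
  v <- array(0.2, dim = c(n, n, 6))
  v[, 6:10, ] <- 0.4  # right half brighter
  st <- band_stack(v, c(490, 550, 680, 720, 800, 900), "reflectance")
  whole <- rect_polygon(0, 0, n, n)
  expect_equal(unname(plot_mean_reflectance(st, whole)), rep(0.3, 6))
  # constant field: any polygon returns the constant
  cst <- make_const_stack(0.2, n = 12)
  expect_equal(unname(plot_mean_reflectance(cst, rect_polygon(1, 1, 7, 5))),
               rep(0.2, 6))
  # exclusion covering the whole plot -> empty region
  expect_error(plot_mean_reflectance(st, whole, exclusion = whole),
               class = "pnc_empty_region")
  # splitting the polygon and area-weighting reproduces the joint mean
  left <- rect_polygon(0, 0, 4, n); right <- rect_polygon(4, 0, n, n)
  ml <- plot_mean_reflectance(st, left); mr <- plot_mean_reflectance(st, right)
  expect_equal((4 * ml + 6 * mr) / 10, plot_mean_reflectance(st, whole))
})

test_that("empirical line round trip recovers reflectance to 1e-8", {
  scene <- panel_scene()
  for (s in 1:5) {
    dn <- default_dn_distortion(seed = s)
    elm <- fit_empirical_line(to_dn(scene$stack, dn), scene$panels)
    back <- apply_empirical_line(to_dn(scene$stack, dn), elm)
    expect_lt(max(abs(back$values - scene$stack$values)), 1e-8)
  }
})

test_that("sensor geometry follows the pinhole footprint model", {
  g <- sensor_geometry(38.26, 30.97, 100, 1280)
  expect_equal(round(unname(g["footprint_x_m"])), 69)
  expect_equal(round(unname(g["footprint_y_m"])), 55)
  expect_equal(round(unname(g["gsd_m"]), 3), 0.054)
  # tan(45 deg) = 1 gives footprint = 2 * altitude
  g2 <- sensor_geometry(90, 90, 1, 2)
  expect_equal(unname(g2), c(2, 2, 1))
  # footprint is linear in altitude
  expect_equal(2 * sensor_geometry(38.26, 30.97, 50, 1280)[1:2],
               sensor_geometry(38.26, 30.97, 100, 1280)[1:2])
  expect_error(sensor_geometry(38, 31, -1, 100),
               class = "pnc_invalid_config")
  expect_error(sensor_geometry(190, 31, 100, 100),
               class = "pnc_invalid_config")
})
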