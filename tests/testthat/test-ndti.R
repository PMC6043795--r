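test_that("NDTI arithmetic, antisymmetry and the degenerate rule", {
  expect_equal(compute_ndti(5, 5), 0)
  expect_equal(compute_ndti(3, 1), 0.5)
  expect_true(is.na(compute_ndti(1, -1)))        # |T1 + T2| < eps
  expect_true(is.na(compute_ndti(1e-13, -1e-13)))
  x <- c(2, 3, 4); y <- c(1, 5, 2)
  expect_equal(compute_ndti(x, y), -compute_ndti(y, x))
})

test_that("the search covers all 780 unordered pairs of 40 features", {
  co <- simulate_texture_cohort(30, seed = 3, size = 32)
  tex <- texture_table(co$stacks, co$polygons)
  rk <- search_ndti(tex, co$truth, top_k = Inf)
  expect_equal(nrow(rk), choose(40, 2))
  expect_equal(nrow(rk), 780L)
  expect_equal(rk$rank, seq_len(780L))
  expect_true(all(diff(rk$r_squared) <= 1e-12))
  # reported orientation always has a non-negative slope
  expect_true(all(rk$slope >= 0))
})

test_that("search R2 matches an independent simple regression to 1e-12", {
  co <- simulate_texture_cohort(30, seed = 4, size = 32)
  tex <- texture_table(co$stacks, co$polygons)
  rk <- search_ndti(tex, co$truth, top_k = 25)
  wide <- stats::reshape(tex[, c("sample_id", "feature", "value")],
                         direction = "wide", idvar = "sample_id",
                         timevar = "feature")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[match(co$truth$sample_id, wide$sample_id), ]
  for (k in seq_len(nrow(rk))) {
    x <- compute_ndti(wide[[rk$T1[k]]], wide[[rk$T2[k]]])
    fit <- slr(x, co$truth$PNC)
    expect_equal(rk$r_squared[k], fit$r_squared, tolerance = 1e-12)
    expect_equal(rk$slope[k], unname(fit$coefficients["x"]),
                 tolerance = 1e-10)
    expect_equal(rk$intercept[k],
                 unname(fit$coefficients["(Intercept)"]), tolerance = 1e-10)
  }
})

test_that("a planted near-noiseless signal is recovered with R2 near 1", {
  # PNC constructed directly from the plots' NDTI(MEA_800, MEA_720)
  co <- simulate_texture_cohort(40, seed = 5, size = 32)
  tex <- texture_table(co$stacks, co$polygons)
  m8 <- tex$value[tex$feature == "MEA_800"]
  m7 <- tex$value[tex$feature == "MEA_720"]
  ids <- tex$sample_id[tex$feature == "MEA_800"]
  truth <- data.frame(sample_id = ids,
                      PNC = 2 * compute_ndti(m8, m7) + 1e-6 * seq_along(ids))
  rk <- search_ndti(tex, truth, top_k = 3)
  expect_equal(sort(c(rk$T1[1], rk$T2[1])), c("MEA_720", "MEA_800"))
  expect_gt(rk$r_squared[1], 0.999999)
})

test_that("constant PNC yields an all-zero but complete ranking", {
  co <- simulate_texture_cohort(10, seed = 6, size = 32)
  tex <- texture_table(co$stacks, co$polygons)
  truth <- data.frame(sample_id = co$truth$sample_id, PNC = 2)
  rk <- search_ndti(tex, truth, top_k = Inf)
  expect_equal(nrow(rk), 780L)
  expect_true(all(rk$r_squared == 0))
  expect_true(all(rk$degenerate))
})

test_that("too few plots is an error", {
  co <- simulate_texture_cohort(4, seed = 7, size = 32)
  tex <- texture_table(co$stacks, co$polygons)
  expect_error(search_ndti(tex, co$truth[1:2, ]),
               class = "pnc_insufficient_plots")
})

test_that("ndti_values evaluates the selected pairs per plot", {
  co <- simulate_texture_cohort(8, seed = 8, size = 32)
  tex <- texture_table(co$stacks, co$polygons)
  sel <- data.frame(T1 = c("MEA_800", "VAR_720"),
                    T2 = c("MEA_720", "VAR_800"))
  nv <- ndti_values(tex, sel)
  expect_equal(names(nv),
               c("sample_id", "NDTI(MEA_800,MEA_720)",
                 "NDTI(VAR_720,VAR_800)"))
  m8 <- tex$value[tex$feature == "MEA_800"][1]
  m7 <- tex$value[tex$feature == "MEA_720"][1]
  expect_equal(nv[["NDTI(MEA_800,MEA_720)"]][1], (m8 - m7) / (m8 + m7))
})
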