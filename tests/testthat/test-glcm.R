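test_that("quantization bins linearly with clamped ends", {
  expect_equal(as.vector(quantize(c(0, 0.5, 1), 2, c(0, 1))), c(0L, 1L, 1L))
  expect_equal(as.vector(quantize(c(0, 1), 64, c(0, 1))), c(0L, 63L))
  expect_equal(as.vector(quantize(c(-5, 7), 8, c(0, 1))), c(0L, 7L))
  q <- quantize(matrix(0.3, 2, 2))
  expect_true(all(q == 0L))
  expect_true(isTRUE(attr(q, "single_level")))
  expect_error(quantize(1, 4, c(1, 0)), class = "pnc_invalid_config")
})

test_that("window GLCM matches exhaustive pair enumeration", {
  cfg <- glcm_config(levels = 2)
  g <- matrix(c(0, 0, 1,
                0, 1, 1,
                0, 0, 0), 3, 3, byrow = TRUE)
  p <- glcm(g, cfg)
  # four valid pairs at (-1,+1): (0,0), (1,1), (0,1), (0,1); symmetrized
  expect_equal(p, brute_glcm(g, 2))
  expect_equal(sum(p), 1)
  # constant grid concentrates all mass on the diagonal cell
  pc <- glcm(matrix(2L, 3, 3), glcm_config(levels = 4))
  expect_equal(pc[3, 3], 1)
  expect_equal(sum(pc), 1)
  # a 1-row grid admits no pair at a row-changing offset
  expect_s3_class(glcm(matrix(0L, 1, 5), cfg), "undefined_texture")
})

test_that("texture measures of canonical matrices evaluate by hand", {
  # constant window: single entry p(c,c) = 1
  m <- glcm_measures(glcm(matrix(3L, 3, 3), glcm_config(levels = 8)))
  expect_equal(unname(m[c("CON", "DIS", "VAR", "ENT")]), c(0, 0, 0, 0))
  expect_equal(unname(m[c("HOM", "SEM")]), c(1, 1))
  expect_equal(unname(m["MEA"]), 3)
  expect_false(attr(m, "cor_defined"))
  # hand evaluation of p = diag(0.5, 0.5)
  p <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
  m2 <- glcm_measures(p)
  expect_equal(unname(m2["ENT"]), log(2))
  expect_equal(unname(m2["SEM"]), 0.5)
  expect_equal(unname(m2["CON"]), 0)
  expect_equal(unname(m2["MEA"]), 0.5)
  expect_equal(unname(m2["COR"]), 1)  # perfectly diagonal
  expect_error(glcm_measures(p * 2), class = "pnc_not_normalized")
})

test_that("engine agrees with the brute-force oracle on random grids", {
  set.seed(101)
  for (i in 1:25) {
    lv <- sample(2:8, 1)
    g <- matrix(sample(0:(lv - 1), 64, TRUE), 8, 8)
    cfg <- glcm_config(levels = lv)
    engine <- glcm_measures(glcm(g, cfg))
    oracle <- brute_measures(brute_glcm(g, lv))
    expect_equal(unname(engine), unname(oracle), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("sliding-window planes equal per-window evaluation", {
  set.seed(7)
  v <- array(stats::runif(34 * 34 * 6), dim = c(34, 34, 6))
  st <- band_stack(v, c(490, 550, 680, 720, 800, 900), "reflectance")
  cfg <- glcm_config(range = c(0, 1), levels = 8)
  tex <- texture_image(st, cfg)
  Q <- quantize(stack_band(st, 720), 8, c(0, 1))
  for (cell in list(c(2, 2), c(17, 5), c(33, 33))) {
    r <- cell[1]; c <- cell[2]
    ref <- glcm_measures(glcm(Q[(r - 1):(r + 1), (c - 1):(c + 1)], cfg))
    got <- vapply(GLCM_MEASURES, function(m) tex$planes[["720"]][[m]][r, c],
                  numeric(1))
    expect_equal(got, ref, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # border pixels are invalid
  expect_true(all(is.na(tex$planes[["720"]]$MEA[1, ])))
  expect_true(all(is.na(tex$planes[["720"]]$MEA[, 34])))
})

test_that("entropy is maximal for a uniform distribution over its support", {
  p <- matrix(1 / 16, 4, 4)
  expect_equal(unname(glcm_measures(p)["ENT"]), log(16))
  # any other 4x4 distribution has lower entropy
  set.seed(3)
  q <- matrix(stats::rexp(16), 4, 4); q <- q / sum(q)
  expect_lt(unname(glcm_measures(q)["ENT"]), log(16) + 1e-12)
})

test_that("CON >= DIS when all level jumps are within one gray level", {
  set.seed(11)
  for (i in 1:10) {
    # smooth grids: neighbouring levels differ by at most 1
    g <- matrix(cumsum(sample(c(0L, 1L), 36, TRUE)) %% 2L, 6, 6)
    m <- glcm_measures(glcm(g, glcm_config(levels = 2)))
    expect_gte(m[["CON"]], m[["DIS"]] - 1e-12)
  }
})

test_that("texture planes cover five bands x eight measures and exclude 900", {
  st <- make_const_stack(0.3)
  tex <- texture_image(st, glcm_config(range = c(0, 1)))
  expect_equal(length(tex$planes) * length(GLCM_MEASURES), 40L)
  expect_error(texture_image(st, glcm_config(), bands = c(720, 900)),
               class = "pnc_excluded_band")
  # constant band propagates the degenerate window measures
  expect_true(all(tex$planes[["490"]]$CON == 0, na.rm = TRUE))
  expect_true(all(tex$planes[["490"]]$HOM == 1, na.rm = TRUE))
  # single-pixel-wide input: no full window anywhere
  thin <- band_stack(array(0.2, c(1, 40, 6)),
                     c(490, 550, 680, 720, 800, 900), "reflectance")
  tthin <- texture_image(thin, glcm_config(range = c(0, 1)))
  expect_true(all(is.na(tthin$planes[["490"]]$MEA)))
})

test_that("plot texture aggregates means over the non-sampling region", {
  st <- make_const_stack(0.3)
  tex <- texture_image(st, glcm_config(range = c(0, 1)))
  polys <- plot_polygons(34)
  ft <- plot_texture(tex, polys$plot, polys$exclusion)
  expect_equal(nrow(ft), 40L)
  expect_equal(ft$value[ft$measure == "HOM"], rep(1, 5))
  expect_equal(ft$value[ft$measure == "MEA"], rep(19, 5))  # level of 0.3
  # area-weighted split invariance on a non-constant plane
  set.seed(5)
  v <- array(stats::runif(34 * 34 * 6), dim = c(34, 34, 6))
  st2 <- band_stack(v, c(490, 550, 680, 720, 800, 900), "reflectance")
  tex2 <- texture_image(st2, glcm_config(range = c(0, 1)))
  top <- rect_polygon(1, 1, 33, 17); bottom <- rect_polygon(1, 17, 33, 33)
  whole <- rect_polygon(1, 1, 33, 33)
  f_top <- plot_texture(tex2, top); f_bot <- plot_texture(tex2, bottom)
  f_all <- plot_texture(tex2, whole)
  # both halves hold the same number of valid interior pixels
  expect_equal((f_top$value + f_bot$value) / 2, f_all$value,
               tolerance = 1e-12)
  expect_error(plot_texture(tex2, rect_polygon(0, 0, 0.5, 0.5)),
               class = "pnc_empty_region")
})

test_that("cohort texture table shares one quantization across plots", {
  co <- simulate_texture_cohort(6, seed = 2, size = 32)
  tt <- texture_table(co$stacks, co$polygons)
  expect_equal(nrow(tt), 6L * 40L)
  expect_setequal(unique(tt$band_nm), c(490, 550, 680, 720, 800))
  rng <- attr(tt, "ranges")
  expect_length(rng, 5L)
  # MEA is comparable across plots: brighter plots have higher MEA_800
  m800 <- tt[tt$feature == "MEA_800", ]
  means <- vapply(co$stacks[m800$sample_id],
                  function(s) mean(stack_band(s, 800)), numeric(1))
  expect_gt(cor(m800$value, means), 0.95)
})
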