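test_that("index formulas reproduce hand-computed values", {
  r <- c(`800` = 0.5, `680` = 0.1, `550` = 0.25, `720` = 0.25,
         `670` = 0.1, `503` = 0.1, `483` = 0.1, `750` = 0.4, `710` = 0.2,
         `570` = 0.12, `531` = 0.12, `434` = 0.1, `496` = 0.12, `401` = 0.1)
  expect_equal(compute_vi(r, "NDVI"), 0.4 / 0.6, tolerance = 1e-10)
  expect_equal(compute_vi(r, "CI_G"), 1)
  # ratio-minus-one identity: equal bands give zero
  r2 <- r; r2["550"] <- 0.5
  expect_equal(compute_vi(r2, "CI_G"), 0)
  expect_equal(compute_vi(r, "PRI"), 0)       # R570 = R531
  expect_equal(compute_vi(r, "NDI_opt"), 0)   # R503 = R483
  expect_equal(compute_vi(r, "OSAVI"), 1.16 * 0.4 / (0.6 + 0.16))
  # VI_opt as printed, including the "+1" term
  expect_equal(compute_vi(r, "VI_opt"), 1.45 * (0.25 + 1) / 0.55)
  expect_equal(compute_vi(r, "VI_opt", viopt_plus_one = FALSE),
               1.45 * 0.25 / 0.55)
  # MTCI as printed: "+" in the denominator
  expect_equal(compute_vi(r, "MTCI"), (0.4 - 0.2) / (0.2 + 0.1))
  expect_equal(compute_vi(r, "BNI"), 0.1 / 0.22)
})

test_that("platform rules: five camera indices, 680 nm surrogate for R670", {
  expect_setequal(vi_names("aerial"),
                  c("NDVI", "CI_G", "CI_RE", "OSAVI", "VI_opt"))
  expect_length(vi_names("ground"), 9L)
  aer <- c(`490` = 0.08, `550` = 0.1, `680` = 0.08, `720` = 0.2,
           `800` = 0.4, `900` = 0.4)
  expect_error(compute_vi(aer, "NDI_opt", platform = "aerial"),
               class = "pnc_platform")
  expect_error(compute_vi(aer, "PRI", platform = "aerial"),
               class = "pnc_platform")
  # aerial OSAVI uses the 680 band where the formula says 670
  expect_equal(compute_vi(aer, "OSAVI", platform = "aerial"),
               1.16 * (0.4 - 0.08) / (0.4 + 0.08 + 0.16))
  expect_error(compute_vi(c(`800` = 0.4), "NDVI"),
               class = "pnc_missing_band")
})

test_that("normalized-difference indices stay within [-1, 1]", {
  set.seed(42)
  for (i in 1:50) {
    r <- stats::runif(14, 0.01, 1)
    names(r) <- c("800", "680", "550", "720", "670", "503", "483", "750",
                  "710", "570", "531", "434", "496", "401")
    for (nm in c("NDVI", "NDI_opt", "PRI"))
      expect_true(abs(compute_vi(r, nm)) <= 1)
  }
})

test_that("aerial and ground agree when band means equal the spectrum", {
  sp <- generate_spectrum(0.65, 2.8, noise_sd = 0)
  centers <- c(490, 550, 680, 720, 800, 900)
  refl <- sample_band(sp, centers)
  names(refl) <- centers
  ground <- sample_band(sp, vi_wavelengths("ground"))
  names(ground) <- vi_wavelengths("ground")
  ground["670"] <- refl[["680"]]  # same surrogate on both platforms
  for (nm in vi_names("aerial"))
    expect_equal(compute_vi(refl, nm, "aerial"),
                 compute_vi(ground, nm, "ground"), tolerance = 1e-6)
})

test_that("vi_table is tidy, complete and rejects duplicates", {
  bands <- data.frame(sample_id = c("a", "b"),
                      `490` = 0.08, `550` = 0.1, `680` = c(0.08, 0.1),
                      `720` = 0.2, `800` = 0.4, `900` = 0.4,
                      check.names = FALSE)
  tab <- vi_table(bands, "aerial")
  expect_equal(nrow(tab), 10L)  # 2 plots x 5 indices
  expect_equal(tab$sample_id, rep(c("a", "b"), each = 5))
  expect_error(vi_table(rbind(bands, bands), "aerial"),
               class = "pnc_duplicate_id")
  empty <- vi_table(bands[0, ], "aerial")
  expect_equal(nrow(empty), 0L)
  # ground tables carry all nine indices
  sp <- list(a = generate_spectrum(0.6, 2, noise_sd = 0))
  gt <- vi_table(spectra_to_bands(sp, vi_wavelengths("ground")), "ground")
  expect_setequal(gt$index, vi_names("ground"))
})
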