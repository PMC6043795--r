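test_that("simple regression matches hand results and the OLS oracle", {
  f <- slr(c(1, 2, 3), c(2, 4, 6))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # hand OLS on three points: R2 = cor^2 = 0.25
  f2 <- slr(c(1, 2, 3), c(1, 3, 2))
  expect_equal(f2$r_squared, 0.25, tolerance = 1e-12)
  expect_error(slr(rep(2, 5), 1:5), class = "pnc_degenerate_fit")
  expect_error(slr(1:2, 1:2), class = "pnc_insufficient_plots")
  # random fixtures against the normal-equation oracle
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rnorm(30); y <- 1.5 * x + stats::rnorm(30)
    f3 <- slr(x, y)
    o <- brute_ols(x, y)
    expect_equal(unname(f3$coefficients), o$coefficients, tolerance = 1e-10)
    expect_equal(f3$r_squared, o$r_squared, tolerance = 1e-10)
  }
})

test_that("stepwise selection never retains more than two predictors", {
  set.seed(31)
  n <- 60
  X <- as.data.frame(matrix(stats::rnorm(n * 6), n))
  names(X) <- paste0("v", 1:6)
  y <- X$v1 + X$v2 + X$v3 + 0.05 * stats::rnorm(n)  # three strong signals
  f <- smlr(X, y)
  expect_lte(length(f$predictors), 2L)
  expect_equal(sort(unname(f$coefficients[f$predictors])), c(1, 1),
               tolerance = 0.2)
})

test_that("stepwise recovers exact low-dimensional structure", {
  # one perfectly collinear candidate is selected alone
  set.seed(32)
  x <- stats::rnorm(40)
  X <- data.frame(a = x, b = stats::rnorm(40))
  f <- smlr(X, 3 * x - 1)
  expect_equal(f$predictors, "a")
  expect_equal(f$r_squared, 1)
  # exact two-variable recovery with orthogonal predictors
  x1 <- rep(c(-1, 1), 20); x2 <- rep(c(-1, -1, 1, 1), 10)
  f2 <- smlr(data.frame(x1 = x1, x2 = x2, junk = stats::rnorm(40)),
             x1 + x2)
  expect_setequal(f2$predictors, c("x1", "x2"))
  expect_equal(f2$r_squared, 1)
  expect_equal(unname(f2$coefficients[c("x1", "x2")]), c(1, 1),
               tolerance = 1e-10)
  # agreement with the normal-equation oracle on the selected columns
  o <- brute_ols(cbind(x1, x2), x1 + x2)
  expect_equal(unname(f2$coefficients[c("(Intercept)", "x1", "x2")]),
               o$coefficients, tolerance = 1e-10)
})

test_that("stepwise returns a flagged intercept-only fit when nothing enters", {
  set.seed(33)
  X <- data.frame(a = stats::rnorm(30), b = stats::rnorm(30))
  f <- smlr(X, stats::rnorm(30), p_enter = 1e-6)
  expect_true(f$empty)
  expect_length(f$predictors, 0L)
  expect_equal(f$r_squared, 0)
})

test_that("RMSE and RRMSE follow their definitions", {
  expect_equal(unname(score(1:4, 1:4)), c(0, 0))
  # residuals {3, 4, 0, 0} with observed mean 5
  O <- c(5, 5, 5, 5); P <- O + c(3, 4, 0, 0)
  expect_equal(unname(score(P, O)), c(2.5, 50))
  # residuals {+1, -1}, observed mean 2
  expect_equal(unname(score(c(3, 1), c(2, 2))), c(1, 50))
  # scaling both P and O scales RMSE, leaves RRMSE unchanged
  s1 <- score(P, O); s2 <- score(3 * P, 3 * O)
  expect_equal(unname(s2["rmse"]), unname(3 * s1["rmse"]))
  expect_equal(s2[["rrmse"]], s1[["rrmse"]])
  expect_error(score(c(1, -1), c(1, -1)), class = "pnc_degenerate_fit")
})

test_that("k-fold CV predicts each sample once, deterministically", {
  set.seed(41)
  d <- data.frame(x = stats::rnorm(45))
  y <- 2 * d$x + 1 + stats::rnorm(45, 0, 0.3)
  a <- kfold_cv(d, y, "x", k = 10, seed = 7)
  b <- kfold_cv(d, y, "x", k = 10, seed = 7)
  expect_identical(a$fold, b$fold)
  expect_identical(a$predicted, b$predicted)
  expect_equal(sort(unique(a$fold)), 1:10)
  expect_equal(sort(as.vector(table(a$fold))), rep(c(4, 5), c(5, 5)))
  c2 <- kfold_cv(d, y, "x", k = 10, seed = 8)
  expect_false(identical(a$fold, c2$fold))
  # perfect predictor: zero error
  p <- kfold_cv(d, 2 * d$x, "x", k = 5, seed = 1)
  expect_equal(p$rmse, 0, tolerance = 1e-10)
  expect_equal(p$rrmse, 0, tolerance = 1e-10)
  expect_error(kfold_cv(d[1:5, , drop = FALSE], y[1:5], "x", k = 10),
               class = "pnc_insufficient_plots")
})

test_that("CV error exceeds in-sample error in expectation", {
  set.seed(51)
  d <- data.frame(x1 = stats::rnorm(40), x2 = stats::rnorm(40))
  y <- d$x1 - 0.5 * d$x2 + stats::rnorm(40, 0, 0.5)
  diffs <- vapply(1:20, function(s) {
    cvr <- kfold_cv(d, y, c("x1", "x2"), k = 10, seed = s)
    fit <- stats::lm(y ~ ., data = d)
    cvr$rmse - sqrt(mean(stats::residuals(fit)^2))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("a two-predictor generative model is recovered within 3 SE", {
  set.seed(61)
  n <- 120
  bni <- stats::runif(n, 0.1, 0.4)
  ndti <- stats::runif(n, -0.3, 0.3)
  y <- 7 * bni + 2 * ndti + 1 + stats::rnorm(n, 0, 0.2)
  f <- smlr(data.frame(BNI = bni, NDTI = ndti), y)
  expect_setequal(f$predictors, c("BNI", "NDTI"))
  fit <- stats::lm(y ~ bni + ndti)
  se <- summary(fit)$coefficients[, 2]
  est <- f$coefficients[c("(Intercept)", "BNI", "NDTI")]
  expect_true(all(abs(est - c(1, 7, 2)) < 3 * se))
})
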