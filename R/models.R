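# Regression and validation: simple linear regression, capped stepwise
# multiple linear regression, k-fold cross-validation, and the RMSE/RRMSE
# scores.

#' Simple linear regression
#'
#' Ordinary least squares of `y` on a single predictor; `r_squared` is the
#' squared Pearson correlation.
#'
#' @param x predictor vector (nonzero variance, n >= 3).
#' @param y response vector.
#' @return a `model_fit`: list with `predictors`, `coefficients` (named,
#'   incl. `(Intercept)`), `r_squared`, `n`.
#' @export
slr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop_pnc("pnc_insufficient_plots", "SLR needs n >= 3 (got %d)", length(x))
  if (stats::var(x) == 0)
    stop_pnc("pnc_degenerate_fit", "predictor has zero variance")
  fit <- stats::lm(y ~ x)
  structure(list(predictors = "x",
                 coefficients = stats::setNames(stats::coef(fit),
                                                c("(Intercept)", "x")),
                 r_squared = if (stats::var(y) == 0) 0
                             else stats::cor(x, y)^2,
                 n = length(x)),
            class = "model_fit")
}

#' Stepwise multiple linear regression capped at two predictors
#'
#' Forward selection with backward elimination: at each step the candidate
#' with the smallest partial-F p-value enters if below `p_enter`; any
#' included variable whose p-value rises above `p_remove` is then dropped.
#' Selection stops at `max_vars` retained predictors (default two, to keep
#' the estimation model simple) or when no candidate qualifies. If nothing
#' enters, the intercept-only fit is returned, flagged.
#'
#' @param candidates data.frame of candidate predictor columns.
#' @param y response vector.
#' @param p_enter,p_remove entry/removal p-value thresholds (0.05 / 0.10).
#' @param max_vars retained-predictor cap.
#' @return a `model_fit` with `predictors`, `coefficients`, `r_squared`,
#'   `n`, and `empty = TRUE` when intercept-only.
#' @export
smlr <- function(candidates, y, p_enter = 0.05, p_remove = 0.10,
                 max_vars = 2L) {
  stopifnot(is.data.frame(candidates), ncol(candidates) >= 1)
  ok <- stats::complete.cases(candidates) & is.finite(y)
  candidates <- candidates[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  if (n <= max_vars + 2)
    stop_pnc("pnc_insufficient_plots",
             "SMLR needs n > max_vars + 2 (got n = %d)", n)
  selected <- character()
  pool <- names(candidates)
  coef_p <- function(vars) {
    # p-values of each term in lm(y ~ vars); exact fits legitimately give
    # p ~ 0, so summary()'s perfect-fit warning is silenced
    fit <- stats::lm(y ~ ., data = candidates[, vars, drop = FALSE])
    s <- suppressWarnings(summary(fit))$coefficients
    stats::setNames(s[-1, 4], rownames(s)[-1])
  }
  repeat {
    if (length(selected) >= max_vars || !length(pool)) break
    entry_p <- vapply(pool, function(v) {
      vars <- c(selected, v)
      p <- coef_p(vars)
      unname(p[length(p)])
    }, numeric(1))
    entry_p[is.na(entry_p)] <- 1
    best <- which.min(entry_p)
    if (entry_p[best] >= p_enter) break
    selected <- c(selected, pool[best])
    pool <- pool[-best]
    # backward pass
    repeat {
      if (length(selected) < 2) break
      p <- coef_p(selected)
      worst <- which.max(p)
      if (p[worst] <= p_remove) break
      dropped <- selected[worst]
      selected <- selected[-worst]
      pool <- c(pool, dropped)
    }
  }
  if (!length(selected)) {
    return(structure(list(predictors = character(),
                          coefficients = c("(Intercept)" = mean(y)),
                          r_squared = 0, n = n, empty = TRUE),
                     class = "model_fit"))
  }
  fit <- stats::lm(y ~ ., data = candidates[, selected, drop = FALSE])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(predictors = selected,
                 coefficients = stats::coef(fit),
                 r_squared = r2,
                 n = n, empty = FALSE),
            class = "model_fit")
}

#' RMSE and relative RMSE of predictions
#'
#' `RMSE = sqrt(mean((P - O)^2))`; `RRMSE = 100 * RMSE / mean(O)`, in
#' percent of the observed mean.
#'
#' @param P predicted values.
#' @param O observed values.
#' @return named vector `rmse`, `rrmse`.
#' @export
score <- function(P, O) {
  stopifnot(length(P) == length(O), length(O) >= 1)
  rmse <- sqrt(mean((P - O)^2))
  if (mean(O) == 0)
    stop_pnc("pnc_degenerate_fit",
             "RRMSE undefined: observed mean is zero")
  c(rmse = rmse, rrmse = 100 * rmse / mean(O))
}

#' k-fold cross-validation of a fixed model form
#'
#' Random seeded partition into `k` near-equal folds; the model (the fixed
#' predictor set — selection is not re-run per fold) is refitted on each
#' training portion and applied to the held-out fold, so every sample is
#' predicted exactly once. Pooled out-of-fold predictions are scored by
#' RMSE/RRMSE and their squared correlation with the observations.
#'
#' @param data data.frame containing the predictor columns.
#' @param y response vector aligned with `data`.
#' @param predictors character vector of column names (the fixed form).
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return a `cv_result`: list with `predicted`, `observed`, `fold`,
#'   `rmse`, `rrmse`, `r_squared`, `k`, `seed`.
#' @export
kfold_cv <- function(data, y, predictors, k = 10L, seed = 1L) {
  ok <- is.finite(y)
  if (length(predictors))
    ok <- ok & stats::complete.cases(data[, predictors, drop = FALSE])
  data <- data[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  if (n < k)
    stop_pnc("pnc_insufficient_plots", "n = %d < k = %d", n, k)
  fold <- with_seed(derive_seed(seed, "cv", k),
                    sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    df_train <- data[!test, predictors, drop = FALSE]
    fit <- if (length(predictors))
      stats::lm(y ~ ., data = cbind(df_train, y = y[!test]))
    else stats::lm(y ~ 1, data = data.frame(y = y[!test]))
    pred[test] <- stats::predict(fit, newdata = data[test, , drop = FALSE])
  }
  sc <- score(pred, y)
  structure(list(predicted = pred, observed = y, fold = fold,
                 rmse = unname(sc["rmse"]), rrmse = unname(sc["rrmse"]),
                 r_squared = if (stats::var(pred) > 0 && stats::var(y) > 0)
                   stats::cor(pred, y)^2 else 0,
                 k = k, seed = seed),
            class = "cv_result")
}
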