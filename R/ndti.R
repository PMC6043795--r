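# Normalized difference texture indices: construction from feature pairs
# and the exhaustive all-pairs search ranked by simple linear fit to PNC.

#' Normalized difference texture index of two feature vectors
#'
#' `NDTI = (T1 - T2) / (T1 + T2)`. Where the denominator is degenerate
#' (`|T1 + T2| < eps`) the value is returned as `NA` rather than a silent
#' near-infinity; downstream regressions drop such plots pairwise.
#'
#' @param t1,t2 numeric vectors of plot-level texture features.
#' @param eps degenerate-denominator threshold.
#' @return numeric vector, `NA` where degenerate.
#' @export
compute_ndti <- function(t1, t2, eps = 1e-12) {
  out <- (t1 - t2) / (t1 + t2)
  out[abs(t1 + t2) < eps] <- NA_real_
  out
}

# Wide feature matrix (plots x features) from a tidy texture table.
feature_matrix <- function(texture) {
  ids <- unique(texture$sample_id)
  feats <- sort(unique(texture$feature))
  m <- matrix(NA_real_, length(ids), length(feats),
              dimnames = list(ids, feats))
  m[cbind(match(texture$sample_id, ids), match(texture$feature, feats))] <-
    texture$value
  m
}

#' Exhaustive NDTI search against PNC for one stage group
#'
#' Builds every unordered pair of the available texture features (780 pairs
#' for the standard 40 features), forms each pair's NDTI across plots, and
#' fits a simple linear regression of PNC on the index. Pairs are reported
#' in the orientation giving a positive slope (ties broken by lexicographic
#' feature name), ranked by R^2 descending.
#'
#' @param texture tidy texture table ([texture_table()] output) for the
#'   samples of one stage group.
#' @param pnc data.frame with `sample_id` and `PNC` columns for the same
#'   samples.
#' @param top_k rows to keep (default 8, mirroring the reported tables);
#'   `Inf` keeps every candidate.
#' @param eps degenerate-denominator threshold for [compute_ndti()].
#' @return data.frame `rank`, `T1`, `T2`, `r_squared`, `slope`, `intercept`,
#'   `n`, with the full feature-pair `r2_matrix` as an attribute.
#' @export
search_ndti <- function(texture, pnc, top_k = 8, eps = 1e-12) {
  m <- feature_matrix(texture)
  keep <- intersect(rownames(m), pnc$sample_id)
  if (length(keep) < 3)
    stop_pnc("pnc_insufficient_plots",
             "need >= 3 plots with PNC and textures (got %d)", length(keep))
  m <- m[keep, , drop = FALSE]
  y <- pnc$PNC[match(keep, pnc$sample_id)]
  feats <- colnames(m)
  pairs <- utils::combn(feats, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    f1 <- pairs[1, k]; f2 <- pairs[2, k]
    x <- compute_ndti(m[, f1], m[, f2], eps)
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      return(data.frame(T1 = f1, T2 = f2, r_squared = 0, slope = 0,
                        intercept = if (n > 0) mean(y[ok]) else NA_real_,
                        n = n, degenerate = TRUE))
    }
    sxy <- stats::cov(x[ok], y[ok])
    slope <- sxy / stats::var(x[ok])
    # report the orientation with positive slope; NDTI(T2,T1) = -NDTI(T1,T2)
    if (slope < 0 || (slope == 0 && f2 < f1)) {
      tmp <- f1; f1 <- f2; f2 <- tmp
      slope <- -slope
      x <- -x
    }
    data.frame(T1 = f1, T2 = f2,
               r_squared = sxy^2 / (stats::var(x[ok]) * stats::var(y[ok])),
               slope = slope,
               intercept = mean(y[ok]) - slope * mean(x[ok], na.rm = TRUE),
               n = n, degenerate = FALSE)
  })
  tab <- do.call(rbind, res)
  r2m <- matrix(NA_real_, length(feats), length(feats),
                dimnames = list(feats, feats))
  for (k in seq_len(nrow(tab))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    r2m[a, b] <- r2m[b, a] <- tab$r_squared[k]
  }
  tab <- tab[order(-tab$r_squared, tab$T1, tab$T2), ]
  tab <- utils::head(tab, if (is.finite(top_k)) top_k else nrow(tab))
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  out <- tab[, c("rank", "T1", "T2", "r_squared", "slope", "intercept",
                 "n", "degenerate")]
  attr(out, "r2_matrix") <- r2m
  out
}

#' NDTI values for named feature pairs
#'
#' Evaluates the indices selected by [search_ndti()] across plots, e.g. to
#' feed the fusion regression.
#'
#' @param texture tidy texture table.
#' @param ranking data.frame with `T1`, `T2` columns (rows of a search
#'   result).
#' @param eps degenerate-denominator threshold.
#' @return data.frame with `sample_id` and one column per pair, named
#'   `"NDTI(T1,T2)"`.
#' @export
ndti_values <- function(texture, ranking, eps = 1e-12) {
  m <- feature_matrix(texture)
  out <- data.frame(sample_id = rownames(m))
  for (k in seq_len(nrow(ranking))) {
    nm <- sprintf("NDTI(%s,%s)", ranking$T1[k], ranking$T2[k])
    out[[nm]] <- compute_ndti(m[, ranking$T1[k]], m[, ranking$T2[k]], eps)
  }
  rownames(out) <- NULL
  out
}
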