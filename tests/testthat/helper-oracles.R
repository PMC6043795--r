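# Independent oracles used across tests. These deliberately re-derive
# results by brute force (explicit loops, normal equations) so they share no
# code path with the package implementations they check.

# Brute-force GLCM: enumerate every pixel pair of `grid` at `offset`,
# tabulate counts, optionally symmetrize, normalize.
brute_glcm <- function(grid, levels, offset = c(-1L, 1L), symmetric = TRUE) {
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(grid))) {
    for (c in seq_len(ncol(grid))) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= nrow(grid) && c2 >= 1 && c2 <= ncol(grid)) {
        counts[grid[r, c] + 1, grid[r2, c2] + 1] <-
          counts[grid[r, c] + 1, grid[r2, c2] + 1] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Brute-force texture measures: direct double sums over the matrix cells.
brute_measures <- function(p) {
  L <- nrow(p)
  mea <- 0; mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    mea <- mea + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  va <- 0; var_j <- 0; hom <- 0; con <- 0; dis <- 0; ent <- 0; sem <- 0
  cov_ij <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    di <- (i - 1) - mea; dj <- (j - 1) - mu_j
    va <- va + di^2 * pij
    var_j <- var_j + dj^2 * pij
    hom <- hom + pij / (1 + ((i - 1) - (j - 1))^2)
    con <- con + ((i - 1) - (j - 1))^2 * pij
    dis <- dis + abs((i - 1) - (j - 1)) * pij
    if (pij > 0) ent <- ent - pij * log(pij)
    sem <- sem + pij^2
    cov_ij <- cov_ij + di * dj * pij
  }
  cor <- if (va > 0 && var_j > 0) cov_ij / sqrt(va * var_j) else 0
  c(MEA = mea, VAR = va, HOM = hom, CON = con, DIS = dis, ENT = ent,
    SEM = sem, COR = cor)
}

# Ordinary least squares by normal equations (independent of stats::lm).
brute_ols <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(coefficients = as.numeric(beta), r_squared = r2)
}

# Tiny single-plot truth row for image/spectrum tests.
make_truth_row <- function(pnc = 2, chl = 0.6, lai = 2.5, het = 0.55,
                           panicle_frac = 0, sample_id = "T_P1") {
  data.frame(sample_id = sample_id, PNC_true = pnc, chl = chl, lai = lai,
             het = het, panicle_frac = panicle_frac)
}

# Constant-valued band stack.
make_const_stack <- function(value = 0.2, n = 34,
                             centers = c(490, 550, 680, 720, 800, 900)) {
  band_stack(array(value, dim = c(n, n, length(centers))), centers,
             "reflectance")
}
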