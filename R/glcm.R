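# Gray-level co-occurrence texture engine: quantization, windowed GLCMs,
# the eight texture measures, sliding-window texture planes, and plot-level
# aggregation.

#' The eight GLCM texture measure names
#'
#' Mean, variance, homogeneity, contrast, dissimilarity, entropy, second
#' moment and correlation — the standard co-occurrence statistics computed
#' per band.
#' @export
GLCM_MEASURES <- c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEM", "COR")

#' GLCM configuration
#'
#' Defaults mirror common practice for this camera: a 3x3 window, the 45
#' degree offset (one row up, one column right in screen coordinates),
#' symmetric pairing, and 64 gray levels binned over a per-band global
#' (image- or cohort-wide) range so the MEA measure is comparable across
#' plots.
#'
#' @param window odd window side in pixels (>= 3).
#' @param offset integer `c(row_step, col_step)`, nonzero; `c(-1, 1)` is the
#'   45 degree direction.
#' @param levels number of gray levels (>= 2).
#' @param range quantization range: `NULL` (auto from the data), a
#'   `c(min, max)` pair applied to every band, or a named list of pairs
#'   keyed by band centre.
#' @param symmetric count each pair in both orientations.
#' @return a `glcm_config` list.
#' @export
glcm_config <- function(window = 3L, offset = c(-1L, 1L), levels = 64L,
                        range = NULL, symmetric = TRUE) {
  if (window < 3L || window %% 2L == 0L)
    stop_pnc("pnc_invalid_config", "window must be odd and >= 3")
  if (levels < 2L)
    stop_pnc("pnc_invalid_config", "gray levels must be >= 2")
  if (all(offset == 0L))
    stop_pnc("pnc_invalid_config", "offset must be nonzero")
  structure(list(window = as.integer(window), offset = as.integer(offset),
                 levels = as.integer(levels), range = range,
                 symmetric = isTRUE(symmetric)),
            class = "glcm_config")
}

#' Quantize a band to integer gray levels
#'
#' Linear binning of `[min, max]` into `levels` half-open bins; values at or
#' beyond the range ends clamp to the end bins. A degenerate range (constant
#' band under auto-range) yields a single-level grid, flagged via the
#' `"single_level"` attribute.
#'
#' @param x numeric matrix (or vector).
#' @param levels number of gray levels.
#' @param range `c(min, max)`; `NULL` uses the data range.
#' @return integer grid of levels in `0 .. levels - 1`.
#' @export
quantize <- function(x, levels = 64L, range = NULL) {
  if (is.null(range)) range <- c(min(x), max(x))
  if (range[2] < range[1])
    stop_pnc("pnc_invalid_config", "quantization max must be >= min")
  if (range[2] == range[1]) {
    q <- x * 0L
    storage.mode(q) <- "integer"
    attr(q, "single_level") <- TRUE
    return(q)
  }
  q <- floor((x - range[1]) / (range[2] - range[1]) * levels)
  q <- pmin(pmax(q, 0), levels - 1L)
  storage.mode(q) <- "integer"
  q
}

#' Co-occurrence matrix of one window grid
#'
#' Counts level pairs `(i, j)` where `j` sits at `offset` from `i`,
#' symmetrizes by adding the transpose when configured, and normalizes to
#' sum 1. Rows/columns index levels `0 .. levels - 1`.
#'
#' @param grid integer gray-level matrix (e.g. one 3x3 window).
#' @param config a [glcm_config()].
#' @return `levels x levels` matrix summing to 1, or the scalar marker
#'   `undefined_texture` when the grid admits no valid pair at the offset.
#' @export
glcm <- function(grid, config = glcm_config()) {
  nr <- nrow(grid); nc <- ncol(grid)
  or <- config$offset[1]; oc <- config$offset[2]
  rows <- seq_len(nr); rows <- rows[rows + or >= 1 & rows + or <= nr]
  cols <- seq_len(nc); cols <- cols[cols + oc >= 1 & cols + oc <= nc]
  if (!length(rows) || !length(cols))
    return(structure(NA, class = "undefined_texture"))
  L <- config$levels
  p <- matrix(0, L, L)
  for (r in rows) for (c in cols) {
    i <- grid[r, c] + 1L
    j <- grid[r + or, c + oc] + 1L
    p[i, j] <- p[i, j] + 1
  }
  if (config$symmetric) p <- p + t(p)
  p / sum(p)
}

#' The eight GLCM texture measures
#'
#' Standard co-occurrence statistics over a normalized matrix `p` with
#' 0-based level indices `i` (row) and `j` (column): mean
#' `MEA = sum(i * p)`, variance `VAR = sum((i - MEA)^2 * p)`, homogeneity
#' `HOM = sum(p / (1 + (i - j)^2))`, contrast `CON = sum((i - j)^2 * p)`,
#' dissimilarity `DIS = sum(|i - j| * p)`, entropy `ENT = -sum(p * ln p)`
#' (with `0 ln 0 = 0`), second moment `SEM = sum(p^2)`, and correlation
#' `COR = sum((i - mu_i)(j - mu_j) p) / (sigma_i sigma_j)`. A degenerate
#' matrix (zero marginal variance) returns `COR = 0`, flagged by the
#' `"cor_defined"` attribute.
#'
#' @param p normalized co-occurrence matrix (must sum to 1).
#' @return named numeric vector of the eight measures, with attribute
#'   `cor_defined`.
#' @export
glcm_measures <- function(p) {
  if (inherits(p, "undefined_texture"))
    stop_pnc("pnc_undefined_texture", "no valid pixel pairs at the offset")
  if (abs(sum(p) - 1) > 1e-8)
    stop_pnc("pnc_not_normalized", "co-occurrence matrix must sum to 1")
  L <- nrow(p)
  i <- matrix(0:(L - 1), L, L)        # row level index
  j <- t(i)                           # column level index
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  nz <- p > 0
  cov_ij <- sum((i - mu_i) * (j - mu_j) * p)
  cor_defined <- var_i > 0 && var_j > 0
  out <- c(
    MEA = mu_i,
    VAR = var_i,
    HOM = sum(p / (1 + (i - j)^2)),
    CON = sum((i - j)^2 * p),
    DIS = sum(abs(i - j) * p),
    ENT = -sum(p[nz] * log(p[nz])),
    SEM = sum(p^2),
    COR = if (cor_defined) cov_ij / sqrt(var_i * var_j) else 0)
  attr(out, "cor_defined") <- cor_defined
  out
}

# Vectorized sliding-window texture for one quantized band. Returns a list
# of full-size matrices (one per measure, NA at invalid border pixels) plus
# a logical matrix marking windows where COR is defined.
band_texture_planes <- function(Q, config) {
  w <- config$window; h <- (w - 1L) %/% 2L
  or <- config$offset[1]; oc <- config$offset[2]
  nr <- nrow(Q); nc <- ncol(Q)
  if (nr < w || nc < w) {
    na <- matrix(NA_real_, nr, nc)
    planes <- stats::setNames(rep(list(na), length(GLCM_MEASURES)),
                              GLCM_MEASURES)
    return(list(planes = planes, cor_valid = matrix(FALSE, nr, nc)))
  }
  ir <- (h + 1L):(nr - h); ic <- (h + 1L):(nc - h)   # interior centres
  # window-relative source cells whose offset partner stays in the window
  wa <- seq_len(w); wa <- wa[wa + or >= 1 & wa + or <= w]
  wb <- seq_len(w); wb <- wb[wb + oc >= 1 & wb + oc <= w]
  Is <- list(); Js <- list()
  for (a in wa) for (b in wb) {
    Jm <- Q[ir + (a - 1L - h), ic + (b - 1L - h), drop = FALSE]
    Im <- Q[ir + (a - 1L - h) + or, ic + (b - 1L - h) + oc, drop = FALSE]
    Js <- c(Js, list(Jm)); Is <- c(Is, list(Im))
    if (config$symmetric) { Js <- c(Js, list(Im)); Is <- c(Is, list(Jm)) }
  }
  S <- length(Is)
  zero <- matrix(0, length(ir), length(ic))
  add <- function(acc, f) { for (s in seq_len(S)) acc <- acc + f(s); acc }
  mu_i <- add(zero, function(s) Is[[s]]) / S
  mu_j <- add(zero, function(s) Js[[s]]) / S
  var_i <- add(zero, function(s) (Is[[s]] - mu_i)^2) / S
  var_j <- add(zero, function(s) (Js[[s]] - mu_j)^2) / S
  hom <- add(zero, function(s) 1 / (1 + (Is[[s]] - Js[[s]])^2)) / S
  con <- add(zero, function(s) (Is[[s]] - Js[[s]])^2) / S
  dis <- add(zero, function(s) abs(Is[[s]] - Js[[s]])) / S
  cov_ij <- add(zero, function(s) (Is[[s]] - mu_i) * (Js[[s]] - mu_j)) / S
  # joint multiplicities: m[s] = how many of the S ordered pairs equal pair s
  keys <- lapply(seq_len(S), function(s)
    Is[[s]] * config$levels + Js[[s]])
  sem <- zero; ent <- zero
  for (s in seq_len(S)) {
    m <- add(zero, function(t) (keys[[s]] == keys[[t]]) + 0)
    sem <- sem + m
    ent <- ent - log(m / S)
  }
  sem <- sem / S^2
  ent <- ent / S
  denom <- sqrt(var_i * var_j)
  cor_valid_in <- denom > 0
  cor <- ifelse(cor_valid_in, cov_ij / ifelse(denom > 0, denom, 1), 0)
  embed <- function(m) {
    full <- matrix(NA_real_, nr, nc)
    full[ir, ic] <- m
    full
  }
  cor_valid <- matrix(FALSE, nr, nc)
  cor_valid[ir, ic] <- cor_valid_in
  list(planes = list(MEA = embed(mu_i), VAR = embed(var_i), HOM = embed(hom),
                     CON = embed(con), DIS = embed(dis), ENT = embed(ent),
                     SEM = embed(sem), COR = embed(cor)),
       cor_valid = cor_valid)
}

#' Sliding-window texture planes for a band stack
#'
#' Quantizes each requested band and computes the eight measures for the
#' window centred on every interior pixel (border pixels are invalid, NA).
#' Texture is computed on the five bands 490/550/680/720/800 nm; the 900 nm
#' band is excluded (it duplicates the 800 nm signal).
#'
#' @param stack reflectance `band_stack`.
#' @param config a [glcm_config()]. Supply an explicit `range` (global or
#'   per band) when plots from one cohort must share a quantization.
#' @param bands band centres to process (default the five texture bands).
#' @return a `texture_planes` list: `planes[[band]][[measure]]` matrices,
#'   `cor_valid[[band]]` masks, the ranges used, and the stack transform.
#' @export
texture_image <- function(stack, config = glcm_config(),
                          bands = TEXTURE_BANDS) {
  if (any(bands == 900))
    stop_pnc("pnc_excluded_band",
             "texture is not computed on the 900 nm band")
  missing <- setdiff(bands, stack$centers)
  if (length(missing))
    stop_pnc("pnc_missing_band", "stack lacks band(s): %s",
             paste(missing, collapse = ", "))
  planes <- list(); cor_valid <- list(); ranges <- list()
  for (b in bands) {
    key <- as.character(b)
    rng <- if (is.list(config$range)) config$range[[key]] else config$range
    band <- stack_band(stack, b)
    if (is.null(rng)) rng <- c(min(band), max(band))
    Q <- quantize(band, config$levels, rng)
    res <- band_texture_planes(Q, config)
    planes[[key]] <- res$planes
    cor_valid[[key]] <- res$cor_valid
    ranges[[key]] <- rng
  }
  structure(list(planes = planes, cor_valid = cor_valid, ranges = ranges,
                 config = config, transform = stack$transform,
                 dim = dim(stack$values)[1:2]),
            class = "texture_planes")
}

#' Plot-level texture features
#'
#' Mean of each per-pixel texture plane over valid pixels inside the plot
#' polygon (minus the exclusion). Border pixels are excluded via the
#' validity mask; COR additionally excludes windows where it is undefined.
#'
#' @param tex a `texture_planes` object from [texture_image()].
#' @param plot_polygon,exclusion xy vertex matrices in the stack frame.
#' @return data.frame `band_nm`, `measure`, `value` (40 rows for the five
#'   bands x eight measures).
#' @export
plot_texture <- function(tex, plot_polygon, exclusion = NULL) {
  stopifnot(inherits(tex, "texture_planes"))
  fake <- list(values = array(0, c(tex$dim, 1)), transform = tex$transform)
  mask <- pixel_mask(fake, plot_polygon, exclusion)
  bands <- names(tex$planes)
  vals <- numeric(length(bands) * length(GLCM_MEASURES))
  k <- 0L
  for (key in bands) {
    for (m in GLCM_MEASURES) {
      plane <- tex$planes[[key]][[m]]
      ok <- mask & !is.na(plane)
      k <- k + 1L
      if (m == "COR") {
        ok_cor <- ok & tex$cor_valid[[key]]
        if (!any(ok) )
          stop_pnc("pnc_empty_region",
                   "no valid texture pixels for COR at %s nm", key)
        # all windows degenerate: COR is the flagged 0 everywhere
        vals[k] <- if (any(ok_cor)) mean(plane[ok_cor]) else 0
        next
      }
      if (!any(ok))
        stop_pnc("pnc_empty_region",
                 "no valid texture pixels for %s at %s nm", m, key)
      vals[k] <- mean(plane[ok])
    }
  }
  data.frame(band_nm = rep(as.numeric(bands), each = length(GLCM_MEASURES)),
             measure = rep(GLCM_MEASURES, times = length(bands)),
             value = vals)
}

#' Cohort texture table
#'
#' Computes plot-level texture features for a set of plot rasters under a
#' shared quantization: unless `config$range` is supplied, the per-band
#' range is taken over all stacks jointly (the cohort-wide analogue of an
#' image-global range), so gray levels mean the same thing in every plot.
#'
#' @param stacks named list of reflectance `band_stack`s keyed by sample id.
#' @param polygons list with `plot` and `exclusion` polygons (shared by all
#'   stacks, as every plot raster uses the same local frame).
#' @param config a [glcm_config()].
#' @param bands texture band centres.
#' @return tidy data.frame: `sample_id`, `band_nm`, `measure`, `value`,
#'   `feature` (e.g. `"MEA_800"`), with the ranges used as an attribute.
#' @export
texture_table <- function(stacks, polygons, config = glcm_config(),
                          bands = TEXTURE_BANDS) {
  if (is.null(config$range)) {
    config$range <- stats::setNames(lapply(bands, function(b) {
      vals <- vapply(stacks, function(s) {
        band <- stack_band(s, b); c(min(band), max(band))
      }, numeric(2))
      c(min(vals[1, ]), max(vals[2, ]))
    }), as.character(bands))
  }
  rows <- lapply(names(stacks), function(id) {
    tex <- texture_image(stacks[[id]], config, bands)
    ft <- plot_texture(tex, polygons$plot, polygons$exclusion)
    ft$sample_id <- id
    ft
  })
  out <- do.call(rbind, rows)
  out$feature <- sprintf("%s_%d", out$measure, out$band_nm)
  out <- out[, c("sample_id", "band_nm", "measure", "feature", "value")]
  attr(out, "ranges") <- config$range
  out
}
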