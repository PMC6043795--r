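# Trial designs: treatment structure of the Rugao rice experiments and the
# synthetic plot layout derived from them.

#' Stage labels and their stage-group membership
#'
#' The season is split at heading: jointing and booting are pre-heading,
#' heading and grain filling are post-heading. "Entire season" is the union
#' of the two groups.
#'
#' @param stages character vector of stage labels.
#' @return character vector of group labels (`"pre-heading"` /
#'   `"post-heading"`), same length as `stages`.
#' @export
stage_group <- function(stages) {
  map <- c(jointing = "pre-heading", booting = "pre-heading",
           heading = "post-heading", filling = "post-heading")
  bad <- setdiff(unique(stages), names(map))
  if (length(bad))
    stop_pnc("pnc_unknown_stage", "unknown stage label(s): %s",
             paste(bad, collapse = ", "))
  unname(map[stages])
}

#' Construct a trial design
#'
#' A design is the treatment structure of one year's experiment: cultivars,
#' nitrogen rates, the planting densities used at each N rate, the replicate
#' count, the plot footprint and the sampled growth stages. Plot count is
#' `replicates * n_cultivars * sum(densities per N rate)`.
#'
#' @param year label for the trial year.
#' @param cultivars character vector of cultivar labels.
#' @param n_rates numeric vector of nitrogen rates (kg N ha^-1).
#' @param density_map named list mapping each N rate (as character) to the
#'   planting densities (plants m^-2) used at that rate.
#' @param replicates number of replicate plots per treatment.
#' @param plot_size plot footprint in metres, `c(width, length)`.
#' @param stages ordered character vector of sampled growth stages.
#' @return a `trial_design` list.
#' @export
trial_design <- function(year, cultivars, n_rates, density_map,
                         replicates = 3L, plot_size = c(5, 6),
                         stages = c("jointing", "booting", "filling")) {
  if (length(cultivars) == 0L || length(n_rates) == 0L)
    stop_pnc("pnc_invalid_config", "cultivars and n_rates must be non-empty")
  if (replicates < 1L)
    stop_pnc("pnc_invalid_config", "replicates must be >= 1")
  missing_rates <- setdiff(as.character(n_rates), names(density_map))
  if (length(missing_rates))
    stop_pnc("pnc_invalid_config", "density_map missing N rate(s): %s",
             paste(missing_rates, collapse = ", "))
  stage_group(stages)  # validates labels
  structure(list(year = as.character(year), cultivars = cultivars,
                 n_rates = n_rates, density_map = density_map,
                 replicates = as.integer(replicates), plot_size = plot_size,
                 stages = stages),
            class = "trial_design")
}

#' The 2015 Rugao trial design
#'
#' Two cultivars; N rates 0/100/200/300 kg N ha^-1, the extremes at a single
#' density (22 plants m^-2), the intermediate rates at two densities (13 and
#' 22); three replicates in 36 plots of 5 x 6 m. Sampled at jointing,
#' booting and filling.
#' @return a `trial_design`.
#' @export
trial_design_2015 <- function() {
  trial_design(
    year = "2015",
    cultivars = c("Wuxiangjing 24", "Yliangyou 1"),
    n_rates = c(0, 100, 200, 300),
    density_map = list(`0` = 22, `100` = c(13, 22),
                       `200` = c(13, 22), `300` = 22),
    replicates = 3L,
    stages = c("jointing", "booting", "filling"))
}

#' The 2016 Rugao trial design
#'
#' Two cultivars, N rates 0/150/300 kg N ha^-1, two densities (13 and 22
#' plants m^-2) at every rate, three replicates. Sampled at jointing,
#' booting, heading and filling.
#' @return a `trial_design`.
#' @export
trial_design_2016 <- function() {
  trial_design(
    year = "2016",
    cultivars = c("Wuxiangjing 24", "Yliangyou 1"),
    n_rates = c(0, 150, 300),
    density_map = list(`0` = c(13, 22), `150` = c(13, 22), `300` = c(13, 22)),
    replicates = 3L,
    stages = c("jointing", "booting", "heading", "filling"))
}

#' Expand a trial design into plot x stage records
#'
#' Enumerates every treatment x replicate as one plot, assigns plots at
#' random to cells of a rectangular field grid (completely randomized), and
#' crosses plots with the design's sampled stages: one output row per plot
#' per sampling date.
#'
#' @param design a [trial_design()].
#' @param seed integer seed controlling plot placement.
#' @return data.frame with columns `sample_id` (plot x date key), `plot_id`,
#'   `year`, `cultivar`, `n_rate`, `density`, `replicate`, `field_row`,
#'   `field_col`, `stage`, `stage_group`.
#' @export
generate_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "trial_design"))
  trt <- do.call(rbind, lapply(design$cultivars, function(cv) {
    do.call(rbind, lapply(design$n_rates, function(nr) {
      data.frame(cultivar = cv, n_rate = nr,
                 density = design$density_map[[as.character(nr)]])
    }))
  }))
  plots <- trt[rep(seq_len(nrow(trt)), each = design$replicates), ]
  plots$replicate <- rep(seq_len(design$replicates), times = nrow(trt))
  n <- nrow(plots)
  plots$plot_id <- sprintf("%s_P%02d", design$year, seq_len(n))
  # randomized placement on the smallest near-square grid that fits
  ncol_f <- ceiling(sqrt(n))
  nrow_f <- ceiling(n / ncol_f)
  cells <- with_seed(derive_seed(seed, "layout", design$year),
                     sample.int(nrow_f * ncol_f, n))
  plots$field_row <- (cells - 1L) %/% ncol_f + 1L
  plots$field_col <- (cells - 1L) %% ncol_f + 1L
  plots$year <- design$year
  out <- merge(plots, data.frame(stage = design$stages), by = NULL)
  out$stage <- factor(out$stage, levels = design$stages)
  out <- out[order(out$plot_id, out$stage), ]
  out$stage <- as.character(out$stage)
  out$stage_group <- stage_group(out$stage)
  out$sample_id <- sprintf("%s_%s", out$plot_id, out$stage)
  rownames(out) <- NULL
  out[, c("sample_id", "plot_id", "year", "cultivar", "n_rate", "density",
          "replicate", "field_row", "field_col", "stage", "stage_group")]
}

#' Number of distinct plots in an expanded design table
#' @param design_rows output of [generate_design()].
#' @return integer plot count.
#' @export
n_plots <- function(design_rows) length(unique(design_rows$plot_id))
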