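# Pipeline orchestration: simulate -> calibrate -> extract -> indices ->
# texture -> NDTI search -> regression models -> report tables.

STAGE_GROUPS <- c("pre-heading", "post-heading", "entire season")

#' Pipeline configuration
#'
#' @param designs list of [trial_design()]s (default the 2015 and 2016
#'   trials).
#' @param seed master seed; all stages derive child streams from it.
#' @param effect an [effect_config()].
#' @param img an [img_config()].
#' @param glcm a [glcm_config()].
#' @param spectrum_noise_sd ground-spectrum noise SD.
#' @param top_k NDTI ranking depth (default 8).
#' @param k cross-validation folds (default 10).
#' @param p_enter,p_remove stepwise thresholds.
#' @param viopt_plus_one see [compute_vi()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(designs = list(trial_design_2015(),
                                           trial_design_2016()),
                            seed = 1L, effect = effect_config(),
                            img = img_config(), glcm = glcm_config(),
                            spectrum_noise_sd = 0.004, top_k = 8, k = 10L,
                            p_enter = 0.05, p_remove = 0.10,
                            viopt_plus_one = TRUE) {
  stopifnot(length(designs) >= 1,
            all(vapply(designs, inherits, logical(1), "trial_design")))
  structure(as.list(environment()), class = "pipeline_config")
}

# Samples belonging to one stage group ("entire season" = all).
group_samples <- function(truth, group) {
  if (group == "entire season") truth$sample_id
  else truth$sample_id[truth$stage_group == group]
}

#' Run the full estimation pipeline on synthetic trials
#'
#' Executes every stage end to end: expands the trial designs, draws organ
#' truth and canopy state, generates ground spectra and DN plot imagery with
#' per-flight calibration panels, fits and applies the empirical line,
#' extracts plot-mean reflectance, computes both platforms' vegetation
#' indices, extracts GLCM texture under a cohort-wide quantization, runs the
#' exhaustive NDTI search per stage group, fits simple and capped stepwise
#' fusion models, and cross-validates the selected model forms. Deterministic
#' for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @return a `pnc_pipeline` list; see the elements `truth`, `ground_bands`,
#'   `aerial_bands`, `vi`, `texture`, `rankings`, `vi_r2`, `models`, `cv`,
#'   `calibration`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  # --- simulate: design, truth, spectra -------------------------------
  design_rows <- do.call(rbind, lapply(config$designs, generate_design,
                                       seed = seed))
  truth <- generate_plot_truth(design_rows, config$effect, seed = seed)
  spectra <- generate_spectra(truth, seed = seed,
                              noise_sd = config$spectrum_noise_sd)

  # --- simulate imagery + calibrate + extract, per flight -------------
  scene <- panel_scene()
  polys <- plot_polygons(config$img$size)
  flights <- unique(truth[, c("year", "stage")])
  stacks <- vector("list", nrow(truth))
  names(stacks) <- truth$sample_id
  calibration <- list()
  for (f in seq_len(nrow(flights))) {
    fl <- flights[f, ]
    fkey <- sprintf("%s_%s", fl$year, fl$stage)
    dn <- default_dn_distortion(derive_seed(seed, "flight", fkey))
    elm <- fit_empirical_line(to_dn(scene$stack, dn), scene$panels)
    calibration[[fkey]] <- elm
    idx <- which(truth$year == fl$year & truth$stage == fl$stage)
    for (i in idx) {
      raw <- generate_ms_image(truth[i, ], spectra[[truth$sample_id[i]]],
                               config$img, dn = dn, seed = seed)
      stacks[[truth$sample_id[i]]] <- apply_empirical_line(raw, elm)
    }
  }
  aerial_means <- t(vapply(stacks, plot_mean_reflectance,
                           numeric(length(MCA6_CENTERS)),
                           plot_polygon = polys$plot,
                           exclusion = polys$exclusion))
  aerial_bands <- data.frame(sample_id = rownames(aerial_means),
                             aerial_means, check.names = FALSE)
  rownames(aerial_bands) <- NULL

  # --- indices --------------------------------------------------------
  ground_bands <- spectra_to_bands(spectra, vi_wavelengths("ground"))
  vi <- rbind(vi_table(ground_bands, "ground", config$viopt_plus_one),
              vi_table(aerial_bands, "aerial", config$viopt_plus_one))

  # --- texture + NDTI search per stage group --------------------------
  texture <- texture_table(stacks, polys, config$glcm)
  pnc <- data.frame(sample_id = truth$sample_id, PNC = truth$PNC_true)
  rankings <- lapply(stats::setNames(STAGE_GROUPS, STAGE_GROUPS),
                     function(g) {
    ids <- group_samples(truth, g)
    search_ndti(texture[texture$sample_id %in% ids, ],
                pnc[pnc$sample_id %in% ids, ], top_k = config$top_k)
  })

  # --- simple linear fits of every VI per group (report table) --------
  # platform-qualified columns: the five camera indices exist on both
  vi$col <- sprintf("%s_%s", vi$index,
                    ifelse(vi$platform == "aerial", "a", "g"))
  vi_wide <- stats::reshape(vi[, c("sample_id", "col", "value")],
                            direction = "wide", idvar = "sample_id",
                            timevar = "col", v.names = "value")
  names(vi_wide) <- sub("^value\\.", "", names(vi_wide))
  vi$col <- NULL
  vi_cols <- setdiff(names(vi_wide), "sample_id")
  vi_r2 <- do.call(rbind, lapply(vi_cols, function(cn) {
    do.call(rbind, lapply(STAGE_GROUPS, function(g) {
      ids <- group_samples(truth, g)
      sel <- vi_wide$sample_id %in% ids
      x <- vi_wide[[cn]][sel]
      y <- pnc$PNC[match(vi_wide$sample_id[sel], pnc$sample_id)]
      fit <- stats::lm(y ~ x)
      data.frame(index = cn, stage_group = g,
                 r_squared = summary(fit)$r.squared,
                 p_value = summary(fit)$coefficients[2, 4],
                 n = length(x))
    }))
  }))
  rownames(vi_r2) <- NULL

  # --- fusion models + cross-validation per group ---------------------
  dat_all <- merge(vi_wide, pnc, by = "sample_id")
  models <- list(); cv <- list()
  for (g in STAGE_GROUPS) {
    ids <- group_samples(truth, g)
    nd <- ndti_values(texture[texture$sample_id %in% ids, ], rankings[[g]])
    names(nd) <- c("sample_id",
                   sprintf("NDTI%d", seq_len(ncol(nd) - 1)))
    dat <- merge(dat_all[dat_all$sample_id %in% ids, ], nd, by = "sample_id")
    ndti_cols <- grep("^NDTI", names(dat), value = TRUE)
    aerial_cols <- grep("_a$", vi_cols, value = TRUE)
    ground_cols <- grep("_g$", vi_cols, value = TRUE)
    combos <- list(
      "UAV"        = c(aerial_cols, ndti_cols),
      "UAV+ground" = c(ground_cols, ndti_cols))
    for (cmb in names(combos)) {
      fit <- smlr(dat[, combos[[cmb]], drop = FALSE], dat$PNC,
                  config$p_enter, config$p_remove, max_vars = 2L)
      cvr <- kfold_cv(dat, dat$PNC, fit$predictors, k = config$k,
                      seed = seed)
      key <- sprintf("%s|%s", cmb, g)
      models[[key]] <- data.frame(
        platform = cmb, stage_group = g,
        formula = format_model(fit), r_squared = fit$r_squared,
        n = fit$n, cv_rmse = cvr$rmse, cv_rrmse = cvr$rrmse,
        cv_r_squared = cvr$r_squared)
      cv[[key]] <- cvr
    }
    # single-index reference models: every aerial VI and the top NDTI
    for (cn in c(aerial_cols, ndti_cols[1])) {
      cvr <- kfold_cv(dat, dat$PNC, cn, k = config$k, seed = seed)
      key <- sprintf("SLR:%s|%s", cn, g)
      models[[key]] <- data.frame(
        platform = sprintf("SLR:%s", cn), stage_group = g,
        formula = cn, r_squared = stats::cor(dat[[cn]], dat$PNC)^2,
        n = nrow(dat), cv_rmse = cvr$rmse, cv_rrmse = cvr$rrmse,
        cv_r_squared = cvr$r_squared)
      cv[[key]] <- cvr
    }
  }
  models <- do.call(rbind, models)
  rownames(models) <- NULL

  ndti_labels <- lapply(rankings, function(rk)
    sprintf("NDTI(%s,%s)", rk$T1, rk$T2))
  manifest <- list(seed = seed,
                   config_hash = hash_object(config),
                   n_samples = nrow(truth),
                   n_per_group = vapply(STAGE_GROUPS, function(g)
                     length(group_samples(truth, g)), numeric(1)))
  structure(list(config = config, truth = truth, spectra = spectra,
                 ground_bands = ground_bands, aerial_bands = aerial_bands,
                 vi = vi, vi_wide = vi_wide, texture = texture, pnc = pnc,
                 polygons = polys, rankings = rankings,
                 ndti_labels = ndti_labels, vi_r2 = vi_r2, models = models,
                 cv = cv, calibration = calibration, manifest = manifest),
            class = "pnc_pipeline")
}

# Human-readable model formula string, e.g.
# "PNC = 4.258*BNI_g + 2.385*NDTI1 - 3.144".
format_model <- function(fit) {
  co <- fit$coefficients
  terms <- co[setdiff(names(co), "(Intercept)")]
  ic <- co[["(Intercept)"]]
  if (!length(terms)) return(sprintf("PNC = %.3f", ic))
  rhs <- paste(sprintf("%.3f*%s", terms, names(terms)), collapse = " + ")
  sprintf("PNC = %s %s %.3f", rhs, if (ic < 0) "-" else "+", abs(ic))
}

# Stable hash of an R object (md5 of its serialization).
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05 (strict
#' inequalities; p = 0.05 is not starred), `"ns"` otherwise.
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Format a report table from pipeline results
#'
#' `"vi_r2"`: the VI-vs-PNC R^2 table (14 index rows, one column pair per
#' stage group, starred by slope significance). `"ndti_top"`: the ranked
#' NDTI table of one stage group (requires `group`). `"smlr_models"`: the
#' fitted model summary.
#'
#' @param kind one of `"vi_r2"`, `"ndti_top"`, `"smlr_models"`.
#' @param results a `pnc_pipeline` object.
#' @param group stage group for `"ndti_top"`.
#' @return data.frame.
#' @export
make_table <- function(kind = c("vi_r2", "ndti_top", "smlr_models"),
                       results, group = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(results, "pnc_pipeline"))
  if (kind == "vi_r2") {
    tab <- results$vi_r2
    out <- data.frame(index = unique(tab$index))
    for (g in STAGE_GROUPS) {
      sel <- tab[tab$stage_group == g, ]
      sel <- sel[match(out$index, sel$index), ]
      gkey <- gsub("[ -]", "_", g)
      out[[paste0("r2_", gkey)]] <- round(sel$r_squared, 2)
      out[[paste0("sig_", gkey)]] <- signif_stars(sel$p_value)
    }
    return(out)
  }
  if (kind == "ndti_top") {
    if (is.null(group) || !group %in% names(results$rankings))
      stop_pnc("pnc_missing_group", "unknown or missing stage group: %s",
               group %||% "<null>")
    return(results$rankings[[group]])
  }
  results$models
}
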