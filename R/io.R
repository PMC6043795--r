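# Output writers: CSV tables, GeoJSON polygons, optional TIFF rasters, and
# the run manifest with checksums.

#' Write a polygon list as GeoJSON
#'
#' Plain planar coordinates (the synthetic plot frame), one Feature per
#' polygon with its properties.
#'
#' @param polygons named list of xy vertex matrices.
#' @param path output file.
#' @param properties optional data.frame of per-feature properties (one row
#'   per polygon).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(polygons, path, properties = NULL) {
  features <- lapply(seq_along(polygons), function(i) {
    ring <- unname(as.matrix(polygons[[i]]))
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    props <- if (is.null(properties)) list(name = names(polygons)[i] %||% i)
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write spectra as a wide CSV
#'
#' One row per sample, one column per wavelength.
#'
#' @param spectra named list of `spectrum` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  wl <- spectra[[1]]$wavelength
  m <- t(vapply(spectra, function(s) s$reflectance, numeric(length(wl))))
  df <- data.frame(sample_id = names(spectra), m, check.names = FALSE)
  names(df) <- c("sample_id", as.character(wl))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a band stack as TIFF (optional)
#'
#' Requires the `tiff` package; writes one multi-sample float TIFF plus a
#' JSON sidecar carrying band centres, kind and the affine transform.
#'
#' @param stack a `band_stack`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_pnc("pnc_missing_dep", "the 'tiff' package is required for TIFF export")
  d <- dim(stack$values)
  planes <- lapply(seq_len(d[3]), function(b) stack$values[, , b])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  jsonlite::write_json(list(centers = stack$centers, kind = stack$kind,
                            transform = stack$transform),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `truth.csv`, `spectra.csv`, `reflectance.csv` (aerial plot means),
#' `vi.csv`, `texture.csv`, `ndti_ranking_<group>.csv` plus the three report
#' tables (`table4.csv`, `table5_<group>.csv`, `table6.csv`),
#' per-model cross-validation scatter tables, `plots.geojson`, `panels.csv`,
#' `calibration.csv` and `manifest.json` with md5 checksums of every file.
#'
#' @param results a `pnc_pipeline` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param spectra write the (large) wide spectra CSV too.
#' @return invisible character vector of written paths.
#' @export
write_pipeline_outputs <- function(results, dir, spectra = FALSE) {
  stopifnot(inherits(results, "pnc_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
    p
  }
  put(results$truth, "truth.csv")
  put(results$aerial_bands, "reflectance.csv")
  put(results$vi, "vi.csv")
  put(results$texture, "texture.csv")
  put(results$vi_r2, "vi_r2.csv")
  put(make_table("vi_r2", results), "table4.csv")
  gkey <- c("pre-heading" = "pre", "post-heading" = "post",
            "entire season" = "all")
  for (g in names(results$rankings)) {
    put(results$rankings[[g]], sprintf("ndti_ranking_%s.csv", gkey[[g]]))
    put(results$rankings[[g]], sprintf("table5_%s.csv", gkey[[g]]))
  }
  put(results$models, "table6.csv")
  for (key in names(results$cv)) {
    cvr <- results$cv[[key]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    put(data.frame(observed = cvr$observed, predicted = cvr$predicted,
                   residual = cvr$predicted - cvr$observed,
                   fold = cvr$fold),
        sprintf("cv_scatter_%s.csv", safe))
  }
  calib <- do.call(rbind, lapply(names(results$calibration), function(k) {
    cbind(flight = k, results$calibration[[k]])
  }))
  put(calib, "calibration.csv")
  p <- file.path(dir, "plots.geojson")
  write_geojson(results$polygons, p)
  paths <- c(paths, p)
  if (spectra) {
    p <- write_spectra_csv(results$spectra, file.path(dir, "spectra.csv"))
    paths <- c(paths, p)
  }
  paths <- unlist(paths)
  manifest <- c(results$manifest,
                list(files = lapply(paths, function(p)
                  list(file = basename(p),
                       md5 = unname(tools::md5sum(p))))))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
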