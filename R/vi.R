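# Vegetation indices: the nine-index library computed from ground
# hyperspectral reflectance, of which five are also computable from the
# six-band camera.

# index -> list(bands = wavelengths required (ground definition),
#               fn = function(r) value, platforms)
vi_registry <- function(viopt_plus_one = TRUE) {
  list(
    NDVI = list(bands = c(680, 800), platforms = c("aerial", "ground"),
                fn = function(r) (r[["800"]] - r[["680"]]) /
                  (r[["800"]] + r[["680"]])),
    CI_G = list(bands = c(550, 800), platforms = c("aerial", "ground"),
                fn = function(r) r[["800"]] / r[["550"]] - 1),
    CI_RE = list(bands = c(720, 800), platforms = c("aerial", "ground"),
                 fn = function(r) r[["800"]] / r[["720"]] - 1),
    OSAVI = list(bands = c(670, 800), platforms = c("aerial", "ground"),
                 fn = function(r) (1 + 0.16) * (r[["800"]] - r[["670"]]) /
                   (r[["800"]] + r[["670"]] + 0.16)),
    VI_opt = list(bands = c(670, 800), platforms = c("aerial", "ground"),
                  fn = function(r) (1 + 0.45) *
                    (r[["800"]]^2 + if (viopt_plus_one) 1 else 0) /
                    (r[["670"]] + 0.45)),
    NDI_opt = list(bands = c(483, 503), platforms = "ground",
                   fn = function(r) (r[["503"]] - r[["483"]]) /
                     (r[["503"]] + r[["483"]])),
    MTCI = list(bands = c(680, 710, 750), platforms = "ground",
                fn = function(r) (r[["750"]] - r[["710"]]) /
                  (r[["710"]] + r[["680"]])),
    PRI = list(bands = c(531, 570), platforms = "ground",
               fn = function(r) (r[["570"]] - r[["531"]]) /
                 (r[["570"]] + r[["531"]])),
    BNI = list(bands = c(401, 434, 496), platforms = "ground",
               fn = function(r) r[["434"]] / (r[["496"]] + r[["401"]]))
  )
}

#' Vegetation index names available on a platform
#'
#' The ground (hyperspectral) platform supports all nine indices; the
#' six-band camera supports only NDVI, CI_G, CI_RE, OSAVI and VI_opt.
#'
#' @param platform `"ground"` or `"aerial"`.
#' @return character vector of index names.
#' @export
vi_names <- function(platform = c("ground", "aerial")) {
  platform <- match.arg(platform)
  reg <- vi_registry()
  names(reg)[vapply(reg, function(d) platform %in% d$platforms, logical(1))]
}

#' Compute one vegetation index
#'
#' Formulas are implemented exactly as tabulated, including
#' `VI_opt = (1 + 0.45) * (R800^2 + 1) / (R670 + 0.45)` and
#' `MTCI = (R750 - R710) / (R710 + R680)`. On the aerial platform the
#' camera's 680 nm band stands in for R670 in OSAVI and VI_opt (the nearest
#' camera band); ground-only indices raise a platform error there.
#'
#' @param reflectances named numeric vector of band reflectances keyed by
#'   wavelength in nm (e.g. `c("680" = 0.08, "800" = 0.45)`).
#' @param index_name one of [vi_names()].
#' @param platform `"ground"` or `"aerial"`.
#' @param viopt_plus_one keep the "+1" term in the tabulated VI_opt formula
#'   (default); `FALSE` switches to the variant without it.
#' @return the index value.
#' @export
compute_vi <- function(reflectances, index_name,
                       platform = c("ground", "aerial"),
                       viopt_plus_one = TRUE) {
  platform <- match.arg(platform)
  reg <- vi_registry(viopt_plus_one)
  def <- reg[[index_name]]
  if (is.null(def))
    stop_pnc("pnc_unknown_index", "unknown vegetation index: %s", index_name)
  if (!platform %in% def$platforms)
    stop_pnc("pnc_platform",
             "%s is not computable on the %s platform", index_name, platform)
  bands <- def$bands
  if (platform == "aerial") bands[bands == 670] <- 680
  have <- names(reflectances)
  missing <- setdiff(as.character(bands), have)
  if (length(missing))
    stop_pnc("pnc_missing_band", "missing band(s) at %s nm for %s",
             paste(missing, collapse = ", "), index_name)
  r <- as.list(reflectances[as.character(bands)])
  names(r) <- as.character(def$bands)  # formula keys (670 even when 680 used)
  unname(def$fn(r))
}

#' Vegetation index table for a cohort
#'
#' One row per sample x index, deterministically ordered. Input is a
#' band-reflectance table (`sample_id` plus wavelength-named columns), e.g.
#' from [spectra_to_bands()] for the ground platform or from plot-mean
#' image reflectance for the aerial platform.
#'
#' @param bands data.frame with `sample_id` and wavelength-named numeric
#'   columns.
#' @param platform `"ground"` or `"aerial"`.
#' @param viopt_plus_one passed to [compute_vi()].
#' @return tidy data.frame: `sample_id`, `platform`, `index`, `value`.
#' @export
vi_table <- function(bands, platform = c("ground", "aerial"),
                     viopt_plus_one = TRUE) {
  platform <- match.arg(platform)
  if (anyDuplicated(bands$sample_id))
    stop_pnc("pnc_duplicate_id", "duplicate sample_id in band table")
  idx <- vi_names(platform)
  if (nrow(bands) == 0L)
    return(data.frame(sample_id = character(), platform = character(),
                      index = character(), value = numeric()))
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    refl <- unlist(bands[i, setdiff(names(bands), "sample_id")])
    data.frame(sample_id = bands$sample_id[i], platform = platform,
               index = idx,
               value = vapply(idx, function(nm)
                 compute_vi(refl, nm, platform, viopt_plus_one), numeric(1)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$index), ]
  rownames(out) <- NULL
  out
}

#' Wavelengths needed to evaluate all indices of a platform
#' @param platform `"ground"` or `"aerial"`.
#' @return sorted integer vector of wavelengths (nm).
#' @export
vi_wavelengths <- function(platform = c("ground", "aerial")) {
  platform <- match.arg(platform)
  reg <- vi_registry()
  bands <- unlist(lapply(vi_names(platform), function(nm) {
    b <- reg[[nm]]$bands
    if (platform == "aerial") b[b == 670] <- 680
    b
  }))
  sort(unique(bands))
}
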