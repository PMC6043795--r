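# Canopy spectra: fixed soil/vegetation endmembers, a linear-mixture
# generator driven by the latent canopy state, and band sampling.

#' Soil endmember reflectance
#'
#' A smooth, slowly brightening loam curve; no absorption features. Used as
#' the background member of the canopy mixture.
#'
#' @param wavelength wavelengths in nm.
#' @return reflectance values in (0, 1).
#' @export
soil_endmember <- function(wavelength) {
  0.10 + 0.22 * (1 - exp(-(wavelength - 350) / 900))
}

#' Green-vegetation endmember reflectance
#'
#' Built from smooth analytic parts: a visible floor with Gaussian
#' chlorophyll absorptions in the blue (~445 nm) and red (~672 nm), a green
#' bump (~555 nm) and a small xanthophyll feature at 531 nm; a logistic red
#' edge whose inflection shifts from ~700 nm toward ~718 nm as the
#' chlorophyll proxy rises; and a near-infrared plateau raised by the
#' leaf-area proxy, declining smoothly into the shortwave infrared.
#'
#' @param wavelength wavelengths (nm).
#' @param chl chlorophyll proxy in `[0, 1]` (deepens absorptions, shifts the
#'   red edge).
#' @param lai leaf-area proxy (raises the NIR plateau).
#' @return reflectance values.
#' @export
veg_endmember <- function(wavelength, chl, lai) {
  w <- wavelength
  depth_red <- 0.155 * (1 - exp(-2.5 * chl))  # saturates at high chlorophyll
  vis <- 0.17 -
    0.19 * chl * exp(-(w - 440)^2 / (2 * 25^2)) -
    depth_red * exp(-(w - 672)^2 / (2 * 36^2)) +
    0.07 * (1 - 0.5 * chl) * exp(-(w - 555)^2 / (2 * 38^2)) -
    0.06 * chl * exp(-(w - 531)^2 / (2 * 14^2))
  # the red-edge inflection moves with pigment AND canopy depth: denser,
  # deeper canopies shift it right just as greener leaves do
  edge <- 1 / (1 + exp(-(w - (697 + 18 * chl + 2.5 * pmin(lai, 5))) / 12))
  nir_level <- 0.28 + 0.12 * tanh((lai - 2.5) / 1.5)
  nir <- nir_level * (1 - 0.45 * stats::plogis((w - 1400) / 250))
  vis * (1 - edge) + nir * edge
}

#' Generate a plot canopy spectrum
#'
#' Linear soil/vegetation mixture on a 1-nm grid. The vegetation cover
#' fraction is `1 - exp(-0.55 * lai)`, so a zero canopy state returns the
#' soil endmember exactly. Emerged panicles (post-heading) add a broad
#' brightening centred in the red/red-edge region, proportional to the
#' panicle biomass fraction. Additive Gaussian noise, clipped to (0, 1).
#'
#' @param chl chlorophyll proxy (0-1), increasing in PNC.
#' @param lai leaf-area proxy.
#' @param panicle_frac panicle share of total dry biomass (0 pre-heading).
#' @param noise_sd additive Gaussian noise SD (reflectance units).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @param wavelengths 1-nm grid (nm), default 350:2500.
#' @return a `spectrum`: list with `wavelength` and `reflectance`.
#' @export
generate_spectrum <- function(chl, lai, panicle_frac = 0, noise_sd = 0.004,
                              seed = 1L, wavelengths = 350:2500) {
  if (noise_sd < 0) stop_pnc("pnc_invalid_config", "noise_sd must be >= 0")
  w <- wavelengths
  f <- 1 - exp(-0.7 * lai)
  rho <- f * veg_endmember(w, chl, lai) + (1 - f) * soil_endmember(w) +
    0.45 * panicle_frac * exp(-(w - 665)^2 / (2 * 85^2))
  if (noise_sd > 0)
    rho <- rho + with_seed(seed, stats::rnorm(length(w), 0, noise_sd))
  structure(list(wavelength = w, reflectance = clip01(rho, 1e-4, 0.9999)),
            class = "spectrum")
}

#' Generate spectra for a truth table
#'
#' One spectrum per row of [generate_plot_truth()] output, seeded per
#' sample.
#'
#' @param truth truth table with `sample_id`, `chl`, `lai`, `panicle_frac`.
#' @param noise_sd,wavelengths passed to [generate_spectrum()].
#' @param seed base seed.
#' @return named list of `spectrum` objects keyed by `sample_id`.
#' @export
generate_spectra <- function(truth, seed = 1L, noise_sd = 0.004,
                             wavelengths = 350:2500) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    generate_spectrum(r$chl, r$lai, r$panicle_frac, noise_sd,
                      seed = derive_seed(seed, "spectrum", r$sample_id),
                      wavelengths = wavelengths)
  })
  names(out) <- truth$sample_id
  out
}

#' Sample a spectrum at a band centre
#'
#' Returns the reflectance at the grid wavelength nearest the requested
#' centre; exact ties break toward the lower wavelength.
#'
#' @param spectrum a `spectrum` object.
#' @param center_nm requested band centre(s), nm.
#' @return reflectance value(s).
#' @export
sample_band <- function(spectrum, center_nm) {
  w <- spectrum$wavelength
  if (any(center_nm < w[1] | center_nm > w[length(w)]))
    stop_pnc("pnc_out_of_range",
             "band centre outside spectrum range [%g, %g] nm",
             w[1], w[length(w)])
  vapply(center_nm, function(cc) {
    d <- abs(w - cc)
    spectrum$reflectance[which.min(d)]  # ascending grid: first min is lower
  }, numeric(1))
}

#' Spectra to a band-reflectance table
#'
#' Samples each spectrum at the given band centres, one row per plot sample.
#'
#' @param spectra named list of `spectrum` objects (names are sample ids).
#' @param centers band centres in nm.
#' @return data.frame with `sample_id` and one numeric column per centre
#'   (named by wavelength).
#' @export
spectra_to_bands <- function(spectra, centers) {
  vals <- t(vapply(spectra, sample_band, numeric(length(centers)),
                   center_nm = centers))
  out <- data.frame(sample_id = names(spectra), vals, check.names = FALSE)
  names(out) <- c("sample_id", as.character(centers))
  rownames(out) <- NULL
  out
}
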