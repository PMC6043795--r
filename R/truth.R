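# Synthetic agronomic truth: organ-level dry weights and N concentrations,
# plant N concentration (PNC), and the latent canopy state that drives the
# spectral and textural generators.

#' Plant nitrogen concentration from organ weights and concentrations
#'
#' PNC is the biomass-weighted mean of the organ N concentrations:
#' `(L_W*L_N + S_W*S_N + P_W*P_N) / (L_W + S_W + P_W)` over leaf, stem and
#' panicle. Organs with zero dry weight contribute nothing; their N
#' concentration may be `NA` (e.g. panicles before heading).
#'
#' @param L_W,S_W,P_W organ dry weights (g), non-negative.
#' @param L_N,S_N,P_N organ N concentrations (% of dry weight).
#' @return PNC in percent, vectorized over plots.
#' @export
compute_pnc <- function(L_W, S_W, P_W, L_N, S_N, P_N = NA_real_) {
  w <- cbind(L_W, S_W, P_W)
  if (any(w < 0, na.rm = TRUE))
    stop_pnc("pnc_invalid_weight", "organ dry weights must be >= 0")
  tot <- L_W + S_W + P_W
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop_pnc("pnc_zero_weight", "total dry weight must be > 0")
  n <- cbind(L_N, S_N, P_N)
  if (any(w > 0 & !is.finite(n)))
    stop_pnc("pnc_missing_organ_n",
             "N concentration missing for an organ with nonzero weight")
  n[w == 0] <- 0  # vacuous term
  as.numeric((w[, 1] * n[, 1] + w[, 2] * n[, 2] + w[, 3] * n[, 3]) / tot)
}

#' Effect configuration for the synthetic truth generator
#'
#' The generative model: organ N concentration = stage baseline +
#' `beta * log1p(n_rate / 100)` + Gaussian noise; organ dry weights are
#' log-normal around stage-specific medians, scaled by N-rate and density
#' multipliers; PNC follows by the weighted-mean identity, so it rises with
#' applied N and is diluted at later stages as stem and panicle biomass
#' accumulates. Latent canopy state: a chlorophyll proxy increasing in PNC,
#' a leaf-area (LAI) proxy increasing with stage, N rate and density, and a
#' heterogeneity scale decreasing with density.
#'
#' @param n_baseline named list of per-stage organ-N baselines (%), elements
#'   `leaf`, `stem`, `panicle`, each a named vector over stages.
#' @param n_beta organ-N response (% per unit `log1p(n_rate/100)`).
#' @param n_noise_sd Gaussian noise SD on organ N (%).
#' @param w_meanlog per-stage log-median organ dry weights (g), same layout
#'   as `n_baseline`; `-Inf` means the organ is absent.
#' @param w_sdlog log-normal SD of organ weights; a scalar or a named
#'   per-organ vector (panicle weight is the most variable organ in the
#'   field — emergence timing differs plot to plot).
#' @param w_nrate_beta,w_density_exp weight multipliers: `1 +
#'   w_nrate_beta*log1p(n_rate/100)` and `(density/22)^w_density_exp`.
#' @param chl_intercept,chl_slope,chl_noise_sd chlorophyll proxy =
#'   `chl_intercept + chl_slope*L_N` + noise, clipped to (0.02, 1). Canopy
#'   greenness follows the leaf N concentration: spectra are dominated by
#'   leaves, so PNC dilution driven by stem/panicle biomass shares is
#'   invisible to them — the mechanism that separates plant-level from
#'   leaf-level N signals at later stages. Since leaf N rises with PNC, the
#'   proxy still increases with PNC in expectation.
#' @param lai_stage per-stage LAI proxy baselines.
#' @param lai_nrate_beta,lai_density_exp,lai_noise_sdlog LAI multipliers and
#'   log-normal noise.
#' @param het_base,het_density_exp heterogeneity scale =
#'   `het_base*(22/density)^het_density_exp`.
#' @return an `effect_config` list.
#' @export
effect_config <- function(
    n_baseline = list(
      leaf    = c(jointing = 3.1, booting = 3.0, heading = 2.6, filling = 2.4),
      stem    = c(jointing = 1.7, booting = 1.5, heading = 1.0, filling = 0.85),
      panicle = c(jointing = NA, booting = NA, heading = 1.3, filling = 1.05)),
    n_beta = c(leaf = 0.50, stem = 0.30, panicle = 0.20),
    n_noise_sd = 0.09,
    w_meanlog = list(
      leaf    = log(c(jointing = 8, booting = 11, heading = 12, filling = 11)),
      stem    = log(c(jointing = 6, booting = 11, heading = 19, filling = 24)),
      panicle = c(jointing = -Inf, booting = -Inf,
                  heading = log(5), filling = log(14))),
    w_sdlog = c(leaf = 0.18, stem = 0.18, panicle = 0.45),
    w_nrate_beta = 0.25,
    w_density_exp = 0.4,
    chl_intercept = 0.10, chl_slope = 0.20, chl_noise_sd = 0.015,
    lai_stage = c(jointing = 1.8, booting = 2.1, heading = 2.9, filling = 3.5),
    lai_nrate_beta = 0.45, lai_density_exp = 0.2, lai_noise_sdlog = 0.08,
    het_base = 0.55, het_density_exp = 0.5) {
  if (n_noise_sd < 0 || any(w_sdlog < 0) || chl_noise_sd < 0 ||
      lai_noise_sdlog < 0)
    stop_pnc("pnc_invalid_config", "noise SDs must be >= 0")
  structure(as.list(environment()), class = "effect_config")
}

#' Generate organ-level truth and latent canopy state for design rows
#'
#' One output row per input row (plot x stage date). Organ N rises
#' monotonically with applied N in expectation; PNC declines at later stages
#' (dilution); panicle weight is zero before heading. `PNC_true` is always
#' [compute_pnc()] applied to the organ fields.
#'
#' @param design_rows output of [generate_design()].
#' @param effect an [effect_config()].
#' @param seed integer seed; each row draws from a child stream derived from
#'   the seed, its plot id and stage, so subsets are reproducible.
#' @return `design_rows` with columns `L_W`, `S_W`, `P_W` (g), `L_N`, `S_N`,
#'   `P_N` (%), `PNC_true` (%), and latent `chl`, `lai`, `het`,
#'   `panicle_frac`.
#' @export
generate_plot_truth <- function(design_rows, effect = effect_config(),
                                seed = 1L) {
  stopifnot(inherits(effect, "effect_config"))
  rows <- lapply(seq_len(nrow(design_rows)), function(i) {
    r <- design_rows[i, ]
    with_seed(derive_seed(seed, "truth", r$plot_id, r$stage), {
      ndose <- log1p(r$n_rate / 100)
      organ_n <- function(organ) {
        base <- effect$n_baseline[[organ]][[r$stage]]
        if (is.na(base)) return(NA_real_)
        clip01(base + effect$n_beta[[organ]] * ndose +
                 stats::rnorm(1, 0, effect$n_noise_sd), 0.05, 9.95)
      }
      organ_w <- function(organ) {
        ml <- effect$w_meanlog[[organ]][[r$stage]]
        if (!is.finite(ml)) return(0)
        mult <- (1 + effect$w_nrate_beta * ndose) *
          (r$density / 22)^effect$w_density_exp
        sdl <- if (length(effect$w_sdlog) > 1L) effect$w_sdlog[[organ]]
               else effect$w_sdlog
        mult * exp(stats::rnorm(1, ml, sdl))
      }
      L_N <- organ_n("leaf"); S_N <- organ_n("stem"); P_N <- organ_n("panicle")
      L_W <- organ_w("leaf"); S_W <- organ_w("stem"); P_W <- organ_w("panicle")
      pnc <- compute_pnc(L_W, S_W, P_W, L_N, S_N, P_N)
      chl <- clip01(effect$chl_intercept + effect$chl_slope * L_N +
                      stats::rnorm(1, 0, effect$chl_noise_sd), 0.02, 1)
      lai <- effect$lai_stage[[r$stage]] *
        (1 + effect$lai_nrate_beta * ndose) *
        (r$density / 22)^effect$lai_density_exp *
        exp(stats::rnorm(1, 0, effect$lai_noise_sdlog))
      het <- effect$het_base * (22 / r$density)^effect$het_density_exp
      data.frame(L_W = L_W, S_W = S_W, P_W = P_W,
                 L_N = L_N, S_N = S_N, P_N = P_N,
                 PNC_true = pnc, chl = chl, lai = lai, het = het,
                 panicle_frac = P_W / (L_W + S_W + P_W))
    })
  })
  cbind(design_rows, do.call(rbind, rows))
}
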