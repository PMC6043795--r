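---
title: "Estimating rice plant nitrogen concentration by fusing spectral indices with UAV image texture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rice plant nitrogen concentration by fusing spectral indices with UAV image texture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pncfusion)
```

## The estimation problem

Plant nitrogen concentration (PNC) is the biomass-weighted mean N
concentration over the organs of the plant,

$$\mathrm{PNC} = \frac{L_W L_N + S_W S_N + P_W P_N}{L_W + S_W + P_W},$$

with $L, S, P$ the leaf, stem and panicle dry weights ($W$, g) and N
concentrations ($N$, %). It is the quantity that N nutrition indices and
in-season fertilizer decisions are built on, and the reference measurement
is destructive (oven-dried organ samples, Kjeldahl digestion).

Remote estimation of PNC is hard for a structural reason: canopy
reflectance is dominated by the leaf layer, while PNC dilutes over the
season mainly because stem and panicle biomass — poor in N and poorly
visible to a nadir sensor — accumulates. Canopy spectra therefore track
leaf N rather than plant N, and their usefulness for PNC degrades after
heading. `pncfusion` implements a two-source remedy:

1. **Spectral vegetation indices (VIs)** from two platforms: nine
   narrow-band indices from ground hyperspectral reflectance (350–2,500 nm)
   and the five of them computable from a six-band UAV camera (490, 550,
   680, 720, 800, 900 nm).
2. **Texture indices** from the UAV imagery: eight gray-level co-occurrence
   (GLCM) measures per band, combined pairwise into normalized difference
   texture indices, $\mathrm{NDTI} = (T_1 - T_2)/(T_1 + T_2)$, selected by
   an exhaustive search over all $\binom{40}{2} = 780$ feature pairs.
3. **Fusion**: stepwise multiple linear regression capped at two
   predictors, per growth-stage group (pre-heading = jointing + booting,
   post-heading = heading + filling, and the entire season), validated by
   seeded 10-fold cross-validation scored with
   $\mathrm{RMSE} = \sqrt{\tfrac1n\sum_i (P_i - O_i)^2}$ and
   $\mathrm{RRMSE} = 100\,\mathrm{RMSE}/\bar O$.

Because no field campaign data are distributed with the package, a seeded
synthetic trial generator reproduces the *design* of the two Rugao
experiments (2015: two cultivars, N rates 0/100/200/300 kg ha⁻¹ with one
density at the extremes and two at the intermediate rates, 3 replicates, 36
plots, sampled at jointing/booting/filling; 2016: two cultivars, 0/150/300
kg ha⁻¹ × two densities, 36 plots, four stages) and the *statistical
structure* the method relies on. Every stage of the workflow is exercisable
and testable offline.

## The texture engine

The GLCM is the normalized joint histogram of quantized gray-level pairs at
a fixed spatial offset. The package uses the conventions most remote-sensing
texture work inherits from ENVI:

* **Quantization** — 64 levels, linear binning over a per-band *global*
  range (here: the min–max over all plot rasters of a run, since plots are
  separate rasters; within one mosaic this is the image range). A global
  range is essential: with per-window ranges the MEA measure would be
  meaningless across plots.
* **Window and offset** — 3×3 sliding window centred on each interior
  pixel; the 45° direction is the offset (−1 row, +1 column) in screen
  coordinates; pairs are counted symmetrically, so the opposite direction
  is included.
* **Measures** — with $p(i,j)$ the normalized matrix and 0-based levels:
  MEA $=\sum i\,p$, VAR $=\sum (i-\mu)^2 p$, HOM $=\sum p/(1+(i-j)^2)$,
  CON $=\sum (i-j)^2 p$, DIS $=\sum |i-j| p$, ENT $=-\sum p\ln p$
  (with $0\ln 0 = 0$), SEM $=\sum p^2$, COR
  $=\sum (i-\mu_i)(j-\mu_j)p/(\sigma_i\sigma_j)$.
* **Degenerate windows** — a constant window has $\sigma_i\sigma_j = 0$;
  COR is returned as 0 there and such windows are excluded from plot means
  through a validity mask, so a few flat windows cannot poison a plot
  aggregate with NaN.
* **Aggregation** — per-pixel texture planes are averaged over the
  *non-sampling* area of the plot polygon (pixel-centre containment), the
  same region used for plot-mean reflectance. Texture is computed on five
  bands only; 900 nm is excluded as nearly collinear with 800 nm. That
  yields 40 features per plot.

Plot-level formulas are checked against a brute-force oracle (explicit
enumeration of all pixel pairs, direct formula sums) to 10⁻¹⁰ in the test
suite, and the sliding-window engine is checked window-by-window against
the single-window path.

In the NDTI search, pairs whose denominator is degenerate
($|T_1 + T_2| < 10^{-12}$, possible with COR features) are dropped
pairwise per candidate and `n` is reported per row. Since
$\mathrm{NDTI}(T_1,T_2) = -\mathrm{NDTI}(T_2,T_1)$ and $R^2$ is invariant
to sign, each unordered pair is evaluated once and reported in the
orientation that makes the regression slope positive (ties break
lexicographically).

## Regression and validation choices

* **Stepwise fusion (SMLR)** — forward entry by smallest partial-$F$
  p-value with `p_enter = 0.05`, backward removal at `p_remove = 0.10`
  (the classic SPSS defaults, configurable), capped at **two** retained
  predictors to keep the estimation model practical. If nothing enters,
  an intercept-only fit is returned, flagged.
* **Fixed-form cross-validation** — variable selection is performed once on
  all data of a stage group; 10-fold CV then refits only the coefficients
  of that fixed form per fold. Fold assignment is a seeded uniform random
  partition into near-equal folds, every sample predicted exactly once.
  Re-running selection inside folds is available in principle but is not
  the validated configuration.
* **Scores** — RMSE and RRMSE over the pooled out-of-fold predictions, plus
  the squared correlation of predictions with observations (CV $R^2$).

## What the synthetic generator emulates

All randomness flows from one integer seed through deterministic child
streams (one per plot × date, per stream label), so any subset of the
cohort is reproducible in isolation and in parallel.

**Agronomy.** Organ N concentration = stage baseline + $\beta \log(1 +
\text{N rate}/100)$ + Gaussian noise (SD 0.09%); organ dry weights are
log-normal around stage medians with N-rate and density multipliers.
Baselines and medians were chosen once for agronomically plausible ranges
(PNC ≈ 1.1–3.3%, declining from jointing to filling; leaf N 2.4–3.9%);
no summary statistics of the original trials are available to match, so
plausibility — not calibration — is the criterion. Panicle weight gets a
larger log-noise (0.45) than leaf/stem (0.18): panicle emergence timing
varies strongly between plots, and this is the main source of post-heading
PNC variance that spectra cannot see.

**Canopy state and spectra.** Three latent variables drive the optics:

* a *chlorophyll proxy* increasing in **leaf** N — deliberately not in PNC
  itself. Canopy reflectance is leaf-dominated; tying greenness to leaf N
  reproduces the leaf/plant divergence that limits spectral PNC estimation
  after heading, while the proxy still rises with PNC in expectation.
* a *leaf-area proxy* (LAI) increasing with stage, N rate and density,
  which sets the vegetation cover fraction $1 - e^{-0.7\,\mathrm{LAI}}$
  and the NIR plateau level;
* a *heterogeneity scale* decreasing with planting density.

Spectra are linear soil/vegetation mixtures of two fixed smooth analytic
endmembers on the 1-nm grid (no radiative-transfer model): Gaussian blue
(440 nm) and red (672 nm) chlorophyll absorptions — the red one saturating
at high chlorophyll, as pigment absorption does — a green bump, a small
531 nm xanthophyll feature, and a logistic red edge whose inflection moves
with chlorophyll *and* canopy depth. That last term matters: red-edge/NIR
indices respond to N strongly where pigment and biomass rise together
(pre-heading) but are structurally confounded across the season.
Post-heading, emerged panicles add a broad red-region brightening
proportional to the panicle biomass fraction. A zero canopy state returns
the soil endmember exactly.

**Imagery.** Each plot raster (default 48×48 px, six bands) is
`mean × illumination × (1 + sd_rel × Z)` plus pixel noise, where the mean
is the plot spectrum sampled at the band centre, `Z` a Gaussian-smoothed
correlated random field, and the illumination factor is common to all
bands of a plot — which is precisely why *normalized* texture indices
outperform single texture features. The relative field SD at 720 nm rises
and at 800 nm falls with PNC: this is the planted, recoverable link between
red-edge/NIR texture contrast and PNC. DN imagery is produced by inverting
a per-flight affine empirical line (gain ≈ 1/1000, 10-bit-like), which the
calibration stage refits from six flat panels (0.03–0.60 reflectance) and
undoes; the round trip is exact to well below 10⁻⁸.

**What passing tests do *not* show.** The generator has no geometric
distortion, no registration error, no BRDF or atmospheric effects, no
weather or phenology model, and its endmembers are analytic conveniences.
Synthetic results demonstrate that the *pipeline* recovers structure it is
known to contain — not that the method attains any particular accuracy on
real canopies. Two known quantitative mismatches with field behaviour are
documented here deliberately: synthetic aerial VIs are somewhat weaker
pre-heading and clearly stronger season-wide than field reports, because
the exact cancellation of stage trends seen in real data is knife-edge and
was not tuned for. The qualitative contrasts the method depends on do hold:
blue/green narrow-band indices (BNI, PRI) work across stage groups, NDTIs
outperform single textures and beat VIs post-heading and season-wide, and
the fused ground-VI + NDTI model dominates every single aerial VI across
the season — with the stepwise search selecting a BNI + NDTI pair, the
same structure the fusion argument predicts.

## Numerical and interface choices

* Reflectance after calibration is clipped to [0, 1] with a clip counter —
  empirical-line extrapolation routinely produces small negatives; erroring
  would be wrong, silence would hide a bad fit.
* Band sampling on the 1-nm grid takes the nearest wavelength, ties toward
  the lower one; hyperspectral input must be on (or resampled to) a 1-nm
  grid, since the instrument's native sampling interval varies.
* `VI_opt` is implemented exactly as tabulated in its source, including the
  "+1" term (`viopt_plus_one = FALSE` switches to the variant without it);
  `MTCI` likewise uses the tabulated "+" denominator. `NDI_opt` uses
  503/483 nm. The aerial OSAVI/VI_opt substitute the camera's 680 nm band
  for the 670 nm the formulas reference — the nearest available band.
* PNC is computed with the panicle term $P_W P_N$; organs with zero weight
  contribute nothing and may have missing N (pre-heading panicles).
* Pixel-in-polygon uses pixel-centre containment, the common
  zonal-statistics default; plot means are therefore exactly linear under
  polygon splitting.
* Significance stars in report tables use strict inequalities
  (p = 0.05 is not starred).
* Problem sizes used by the packaged workflow: 252 plot × date samples
  (two years), 48×48 px plot rasters, 64 gray levels, and 50 replicates of
  200-plot cohorts for the planted-signal recovery experiment. These are
  the scales the package's own analyses and acceptance script run at.

## Known limitations

* The two orientation/asymmetry questions inherited from practice — whether
  an exhaustive texture-pair search should treat ordered pairs separately,
  and how negative-valued COR features should be handled in ratios — are
  resolved here as: unordered pairs, positive-slope reporting, and
  pairwise-dropped degenerate denominators. Other conventions would change
  reported orientations but not rankings.
* Bit-exact replication of any particular commercial texture implementation
  is not attempted; the co-occurrence definitions above are the standard
  ones, and the oracle tests pin the package to them.
* The stepwise cap of two predictors is a modelling choice for parsimony,
  not a statistical optimum; with the cap removed the selection behaves as
  ordinary forward/backward stepwise OLS.
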