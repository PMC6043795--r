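# pncfusion

Estimating rice **plant nitrogen concentration (PNC)** by fusing spectral
vegetation indices with gray-level co-occurrence (GLCM) texture indices from
six-band UAV imagery.

PNC — the biomass-weighted mean N concentration over leaf, stem and panicle,

```
PNC = (L_W·L_N + S_W·S_N + P_W·P_N) / (L_W + S_W + P_W)   [%]
```

— is the reference quantity for in-season rice N management, but it is
measured destructively. Spectral vegetation indices estimate it well only
before heading: canopy reflectance is dominated by leaves, so the dilution
of PNC by stem and panicle biomass after heading is largely invisible to
spectra, and structure-sensitive indices saturate. This package implements
the fusion remedy: image **texture** carries canopy-structure information
that spectra lose, and normalized difference texture indices

```
NDTI = (T1 − T2) / (T1 + T2)
```

over pairs of GLCM features (8 measures × 5 bands = 40 features, 780
unordered pairs searched exhaustively per growth-stage group) combine with
narrow-band ground indices — above all the blue N index,
`BNI = R434 / (R496 + R401)` — in a stepwise regression capped at two
predictors, validated by seeded 10-fold cross-validation (RMSE, RRMSE).

Who this is for: crop phenotyping and precision-agriculture researchers who
want a tested, reproducible reference implementation of the VI + GLCM + NDTI
+ stepwise-fusion workflow, including a seeded synthetic trial generator so
the entire pipeline runs offline with no field data.

## What's in the box

| Piece | Contents |
|---|---|
| `R/` | the package: trial designs, organ-level truth + canopy-state generator, spectra, textured multiband plot rasters, empirical-line calibration, zonal statistics, the GLCM engine, NDTI search, SLR/SMLR/k-fold CV, pipeline + report tables |
| `analysis/01…06_*.R` | the staged workflow: simulate → calibrate/extract → indices → texture → NDTI search → fusion models; writes its tables under `results/` |
| `tests/testthat/` | unit, property and acceptance tests (brute-force GLCM and normal-equation OLS oracles) |
| `scripts/acceptance.R` | recomputes the headline numbers from scratch (below) |
| `vignettes/pnc-texture-fusion.Rmd` | the methods vignette: model, conventions, generator design, limitations |

## Worked example

```r
library(pncfusion)

# sensor geometry of the six-band camera at 100 m
sensor_geometry(38.26, 30.97, altitude_m = 100, pixels_x = 1280)
#> footprint_x_m footprint_y_m         gsd_m
#>   69.37350751   55.40852609    0.05419805

# the full synthetic workflow: 2015 + 2016 trials, 252 plot x date samples
res <- run_pipeline(pipeline_config(seed = 1))

# ranked NDTI search, entire season (top of 780 candidates)
head(res$rankings[["entire season"]][, 1:6], 3)
#>   rank      T1      T2 r_squared     slope intercept
#> 1    1 HOM_800 MEA_680 0.8605132  9.235557 10.509069
#> 2    2 SEM_800 MEA_680 0.8602375 19.706696 20.987170
#> 3    3 ENT_490 MEA_680 0.8396067  3.817990  4.855527

# fused two-predictor models selected by capped stepwise regression
m <- res$models
m[m$platform == "UAV+ground", c("stage_group", "formula", "cv_rmse", "cv_rrmse")]
#>     stage_group                                  formula   cv_rmse cv_rrmse
#>     pre-heading  PNC = -2.692*BNI_g + 0.778*NDTI6 + 3.140 0.2031979 7.499773
#>    post-heading  PNC = 1.604*NDTI1 + -2.670*BNI_g + 1.765 0.1388196 8.556174
#>   entire season PNC = 8.741*NDTI1 + -1.296*BNI_g + 10.264 0.2210448 9.852429
```

The numbers read as: one image pixel covers 5.4 cm at 100 m flight height;
the best season-wide texture index alone explains 86% of PNC variance in the
synthetic cohort; and in every stage group the stepwise search lands on a
blue N index + NDTI pair, predicting PNC with a cross-validated error around
0.14–0.22 percentage points (8–10% of the mean) — while the best *single*
aerial VI reaches only CV R² ≈ 0.67 across the season. The same staged
computation, with commentary, is in `analysis/01_simulate.R` …
`analysis/06_fit_models.R` (run them in order from the repository root).

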