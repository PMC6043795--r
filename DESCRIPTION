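Package: pncfusion
Title: Rice Plant Nitrogen Concentration from Spectral Indices and UAV Image Texture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plant nitrogen concentration (PNC) in rice by fusing
    spectral vegetation indices, computed from ground hyperspectral canopy
    reflectance and UAV six-band multispectral imagery, with normalized
    difference texture indices (NDTI) derived from gray-level co-occurrence
    matrix (GLCM) texture of the UAV bands. Provides a seeded synthetic field
    trial generator (design tables, organ-level nitrogen data, canopy spectra,
    calibration panels, textured plot rasters), empirical-line radiometric
    calibration, plot-level zonal statistics, a from-scratch GLCM texture
    engine, an exhaustive NDTI pair search ranked by simple linear regression
    fit per growth-stage group, capped stepwise multiple linear regression,
    and k-fold cross-validation scored by RMSE and relative RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml
Config/testthat/edition: 3
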