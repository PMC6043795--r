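#!/usr/bin/env Rscript
# Stage 1 -- simulate the two synthetic rice trials.
#
# Expands the 2015 and 2016 treatment structures (N rate x density x
# cultivar, replicated), draws organ dry weights and N concentrations per
# plot and sampling date, derives PNC and the latent canopy state, and
# generates ground hyperspectral spectra plus DN plot imagery with
# per-flight calibration panels.

source("analysis/_common.R")

design <- do.call(rbind, lapply(CFG$designs, generate_design, seed = SEED))
truth <- generate_plot_truth(design, CFG$effect, seed = SEED)
spectra <- generate_spectra(truth, seed = SEED,
                            noise_sd = CFG$spectrum_noise_sd)

message(sprintf("simulated %d plots x dates (%d plots 2015, %d plots 2016)",
                nrow(truth),
                n_plots(design[design$year == "2015", ]),
                n_plots(design[design$year == "2016", ])))
message(sprintf("PNC range %.2f-%.2f%%; stage means: %s",
                min(truth$PNC_true), max(truth$PNC_true),
                paste(sprintf("%s %.2f", names(tm <- tapply(
                  truth$PNC_true, truth$stage, mean)), tm), collapse = ", ")))

# DN imagery, one calibration (panel scene + distortion) per flight
scene <- panel_scene()
flights <- unique(truth[, c("year", "stage")])
dn_stacks <- list(); distortions <- list()
for (f in seq_len(nrow(flights))) {
  fl <- flights[f, ]
  fkey <- sprintf("%s_%s", fl$year, fl$stage)
  distortions[[fkey]] <- default_dn_distortion(derive_seed(SEED, "flight",
                                                           fkey))
  for (i in which(truth$year == fl$year & truth$stage == fl$stage)) {
    id <- truth$sample_id[i]
    dn_stacks[[id]] <- generate_ms_image(truth[i, ], spectra[[id]],
                                         CFG$img, dn = distortions[[fkey]],
                                         seed = SEED)
  }
}
message(sprintf("generated %d DN plot rasters over %d flights",
                length(dn_stacks), nrow(flights)))

write_result(truth, "truth.csv")
write_result(data.frame(panel = seq_len(nrow(scene$panels$reflectance)),
                        reflectance = scene$panels$reflectance[, 1]),
             "panels.csv")
polys <- plot_polygons(CFG$img$size)
write_geojson(polys, file.path(RESULTS, "plots.geojson"))
write_spectra_csv(spectra, file.path(RESULTS, "spectra.csv"))

save_state(list(truth = truth, spectra = spectra, scene = scene,
                flights = flights, distortions = distortions,
                dn_stacks = dn_stacks, polys = polys), "simulated")
message("done.")
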