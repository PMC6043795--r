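#!/usr/bin/env Rscript
# Stage 2 -- radiometric calibration and plot reflectance extraction.
#
# Fits the empirical line (reflectance = gain * DN + offset) per flight from
# the six calibration panels, applies it to every DN plot raster, and
# averages reflectance over the non-sampling area of each plot.

source("analysis/_common.R")

st <- load_state("simulated")

calibration <- list()
stacks <- list()
for (fkey in names(st$distortions)) {
  dn <- st$distortions[[fkey]]
  elm <- fit_empirical_line(to_dn(st$scene$stack, dn), st$scene$panels)
  calibration[[fkey]] <- cbind(flight = fkey, elm)
  parts <- strsplit(fkey, "_")[[1]]
  ids <- st$truth$sample_id[st$truth$year == parts[1] &
                              st$truth$stage == parts[2]]
  for (id in ids) stacks[[id]] <- apply_empirical_line(st$dn_stacks[[id]], elm)
}
calib <- do.call(rbind, calibration)
message(sprintf("calibrated %d flights; all per-band line fits R2 >= %.6f",
                length(st$distortions), min(calib$r_squared)))

means <- t(vapply(stacks, plot_mean_reflectance, numeric(6),
                  plot_polygon = st$polys$plot,
                  exclusion = st$polys$exclusion))
reflectance <- data.frame(sample_id = rownames(means), means,
                          check.names = FALSE)
rownames(reflectance) <- NULL
message(sprintf("extracted plot-mean reflectance for %d samples x 6 bands",
                nrow(reflectance)))

write_result(calib, "calibration.csv")
write_result(reflectance, "reflectance.csv")
save_state(list(stacks = stacks, reflectance = reflectance), "calibrated")
message("done.")
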