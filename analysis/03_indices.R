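#!/usr/bin/env Rscript
# Stage 3 -- vegetation indices from both platforms, and their simple
# linear fits to PNC per stage group (the Table-4-style summary).

source("analysis/_common.R")

st <- load_state("simulated")
cal <- load_state("calibrated")

ground_bands <- spectra_to_bands(st$spectra, vi_wavelengths("ground"))
vi <- rbind(vi_table(ground_bands, "ground"),
            vi_table(cal$reflectance, "aerial"))
write_result(vi, "vi.csv")
message(sprintf("computed %d VI values (9 ground + 5 aerial indices)",
                nrow(vi)))

# SLR of PNC on each index per stage group, starred by slope significance
vi$col <- sprintf("%s_%s", vi$index, ifelse(vi$platform == "aerial",
                                            "a", "g"))
pnc <- data.frame(sample_id = st$truth$sample_id, PNC = st$truth$PNC_true)
groups <- list("pre-heading" = c("jointing", "booting"),
               "post-heading" = c("heading", "filling"),
               "entire season" = unique(st$truth$stage))
tab <- do.call(rbind, lapply(unique(vi$col), function(cn) {
  v <- vi[vi$col == cn, ]
  do.call(rbind, lapply(names(groups), function(g) {
    ids <- st$truth$sample_id[st$truth$stage %in% groups[[g]]]
    x <- v$value[match(ids, v$sample_id)]
    y <- pnc$PNC[match(ids, pnc$sample_id)]
    fit <- summary(stats::lm(y ~ x))
    data.frame(index = cn, stage_group = g,
               r_squared = fit$r.squared,
               sig = signif_stars(fit$coefficients[2, 4]))
  }))
}))
write_result(tab, "table4.csv")

best <- do.call(rbind, lapply(split(tab, tab$stage_group), function(s)
  s[which.max(s$r_squared), ]))
message("best index per stage group:")
for (i in seq_len(nrow(best)))
  message(sprintf("  %-14s %s (R2 = %.2f)", best$stage_group[i],
                  best$index[i], best$r_squared[i]))
message("done.")
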