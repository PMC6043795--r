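#!/usr/bin/env Rscript
# Stage 4 -- GLCM texture extraction.
#
# Quantizes the five texture bands (490/550/680/720/800 nm; 900 nm is
# excluded as redundant with 800 nm) to 64 gray levels over a cohort-wide
# per-band range, computes the eight co-occurrence measures in a sliding
# 3x3 window at the 45-degree offset, and averages each texture plane over
# the non-sampling area of every plot.

source("analysis/_common.R")

st <- load_state("simulated")
cal <- load_state("calibrated")

texture <- texture_table(cal$stacks, st$polys, CFG$glcm)
write_result(texture, "texture.csv")

rng <- attr(texture, "ranges")
message(sprintf("extracted %d plot-level texture features (%d plots x 40)",
                nrow(texture), length(unique(texture$sample_id))))
message("cohort quantization ranges per band:")
for (b in names(rng))
  message(sprintf("  %s nm: [%.3f, %.3f]", b, rng[[b]][1], rng[[b]][2]))

save_state(texture, "texture")
message("done.")
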