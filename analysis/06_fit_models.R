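#!/usr/bin/env Rscript
# Stage 6 -- fusion models and cross-validation.
#
# Per stage group, fits capped (two-variable) stepwise regressions of PNC on
# (a) aerial VIs + top NDTIs and (b) ground VIs + top NDTIs, plus
# single-index reference models, and scores every fixed model form by
# seeded 10-fold cross-validation (RMSE, RRMSE, CV R2). The headline
# comparison - season-wide fusion vs the best single aerial VI - is printed
# at the end.

source("analysis/_common.R")

res <- suppressWarnings(run_pipeline(CFG))

write_result(res$models, "table6.csv")
for (key in names(res$cv)) {
  cvr <- res$cv[[key]]
  safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
  write_result(data.frame(observed = cvr$observed,
                          predicted = cvr$predicted,
                          residual = cvr$predicted - cvr$observed,
                          fold = cvr$fold),
               sprintf("cv_scatter_%s.csv", safe))
}

m <- res$models
fused <- m[m$platform %in% c("UAV", "UAV+ground"), ]
message("fusion models (stepwise, at most two predictors):")
for (i in seq_len(nrow(fused)))
  message(sprintf("  %-11s %-14s %s  [R2 = %.2f, CV RMSE = %.3f, RRMSE = %.1f%%]",
                  fused$platform[i], fused$stage_group[i], fused$formula[i],
                  fused$r_squared[i], fused$cv_rmse[i], fused$cv_rrmse[i]))

season <- m[m$stage_group == "entire season", ]
best_aerial <- max(season$cv_r_squared[grepl("^SLR:", season$platform) &
                                         grepl("_a$", season$platform)])
fused_cv <- season$cv_r_squared[season$platform == "UAV+ground"]
message(sprintf(
  "entire season: fused ground-VI + NDTI CV R2 = %.3f vs best single aerial VI CV R2 = %.3f (difference %.3f)",
  fused_cv, best_aerial, fused_cv - best_aerial))
message("done.")
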