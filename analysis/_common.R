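# Shared settings for the analysis scripts. Run the scripts from the
# repository root in numeric order; intermediate state is cached under
# results/state/ so each stage can be rerun alone.

library(pncfusion)

SEED <- 1L
RESULTS <- "results"
STATE <- file.path(RESULTS, "state")
dir.create(STATE, recursive = TRUE, showWarnings = FALSE)

CFG <- pipeline_config(seed = SEED)

state_path <- function(name) file.path(STATE, paste0(name, ".rds"))
load_state <- function(name) {
  p <- state_path(name)
  if (!file.exists(p))
    stop(sprintf("missing %s - run the earlier analysis scripts first", p))
  readRDS(p)
}
save_state <- function(object, name) saveRDS(object, state_path(name))

write_result <- function(df, name) {
  p <- file.path(RESULTS, name)
  utils::write.csv(df, p, row.names = FALSE)
  message("  wrote ", p)
}
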