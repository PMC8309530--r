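# Shared setup for the analysis drivers: the full-protocol synthetic
# cohort (20 subjects; session 1 = 10 min rest + three 2-min movement
# blocks, session 2 = 5 min rest; three placements; 500 Hz) and the
# experiment configuration used throughout (8-min training, 2-min test
# blocks, k = 20, alpha = "auto", 20 symbols, Butterworth 8 / 40 Hz).
#
# The cohort is ~38M samples; it is generated once and cached as an RDS
# under scratch/ so the downstream drivers can reuse it.

library(nrcid)

MASTER_SEED <- 42L

get_cohort <- function() {
  cache <- file.path("scratch", sprintf("cohort_seed%d.rds", MASTER_SEED))
  if (file.exists(cache)) {
    message("loading cached cohort: ", cache)
    return(readRDS(cache))
  }
  message("generating full-protocol cohort (this takes a minute) ...")
  co <- generate_cohort(cohort_spec(seed = MASTER_SEED))
  dir.create("scratch", showWarnings = FALSE)
  saveRDS(co, cache)
  co
}

full_cfg <- function(...) experiment_config(...)

ensure_results <- function() dir.create("results", showWarnings = FALSE)
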