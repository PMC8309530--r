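# Shared small synthetic cohorts, generated once per test run. Sizes are
# kept well below the full protocol (8 subjects, 3-minute rest blocks) so
# the experiment tests stay fast; the acceptance tests use a larger
# cohort of their own.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, spec_fn) {
  if (is.null(.cohort_cache[[name]]))
    .cohort_cache[[name]] <- spec_fn()
  .cohort_cache[[name]]
}

small_cohort_spec <- function(seed = 7, ...) {
  cohort_spec(n_subjects = 8, rest1_duration = 180, move_duration = 60,
              rest2_duration = 120, seed = seed, ...)
}

small_cohort <- function() {
  cached_cohort("base", function() generate_cohort(small_cohort_spec()))
}

# Control cohort: no movement artifacts at all.
no_artifact_cohort <- function() {
  cached_cohort("no_artifact", function() {
    ap <- cohort_spec()$acq_params
    for (mv in names(ap$artifact))
      for (pl in names(ap$artifact[[mv]]))
        ap$artifact[[mv]][[pl]] <- 0
    generate_cohort(small_cohort_spec(acq_params = ap))
  })
}

# Control cohort: no session-to-session drift.
no_drift_cohort <- function() {
  cached_cohort("no_drift", function() {
    ap <- cohort_spec()$acq_params
    ap$session_drift_sd <- 0
    generate_cohort(small_cohort_spec(acq_params = ap))
  })
}

small_cfg <- function(...) {
  experiment_config(train_duration = 120, test_duration = 60, ...)
}
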