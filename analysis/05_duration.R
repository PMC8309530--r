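# Duration sweep: how much ECG does a probe need?
#
# The 2-minute test blocks are split into non-overlapping segments of
# each grid duration; every segment is identified and a subject's
# decision is the majority vote over its segments. The different-session
# variant (the realistic deployment setting) uses an extended grid down
# to 1 s; the same-session variant uses the standard grid for the paired
# comparison.

source("analysis/00_common.R")
ensure_results()

co <- get_cohort()

message("different-session sweep (extended grid) ...")
ds_diff <- run_duration_sweep(
  co, full_cfg(duration_grid = c(60, 30, 15, 10, 8, 6, 5, 4, 3, 2, 1)),
  variants = "different")

message("same-session sweep (standard grid) ...")
ds_same <- run_duration_sweep(
  co, full_cfg(duration_grid = c(60, 30, 15, 10, 8, 6, 4, 2)),
  variants = "same")

both <- rbind(ds_diff$cells, ds_same$cells)
write.csv(both, "results/duration_sweep.csv", row.names = FALSE)
curve <- both[, c("session", "placement", "duration", "f1")]
names(curve) <- c("session", "placement", "duration", "F1score")
write.csv(curve, "results/duration_curve.csv", row.names = FALSE)
message("wrote results/duration_sweep.csv and results/duration_curve.csv")

for (pl in ecg_placements()) {
  d <- ds_diff$cells[ds_diff$cells$placement == pl, ]
  message(sprintf(
    "%s (different session): per-segment accuracy %.2f @2s -> %.2f @10s -> %.2f @60s",
    pl, d$segment_accuracy[d$duration == 2],
    d$segment_accuracy[d$duration == 10],
    d$segment_accuracy[d$duration == 60]))
}
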