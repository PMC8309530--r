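# Placement-transfer study: can a model trained on chest ECG identify
# subjects from simultaneously recorded finger/wrist ECG?
#
# Chest-trained references, tested on the same-session rest tail of the
# other two placements. The same-placement chest cell is the control.

source("analysis/00_common.R")
ensure_results()

co <- get_cohort()
tr <- run_placement_transfer(co, full_cfg())
print(tr)
report_studies(tr, "results")
message("wrote results/placement_transfer.csv")

message(sprintf("same-placement control error: %.2f", tr$baseline$error))
for (i in seq_len(nrow(tr$cells)))
  message(sprintf("chest -> %s transfer error: %.2f (chance would be %.2f)",
                  tr$cells$test_placement[i], tr$cells$error[i],
                  1 - 1 / tr$reports[[1]]$n_subjects))
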