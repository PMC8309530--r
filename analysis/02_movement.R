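# Movement study: how does movement during acquisition degrade
# identification, per electrode placement?
#
# Per placement, subject models are trained on the first 8 minutes of
# session-1 rest and each subject's 2-minute movement block is
# identified. The expectation encoded in the generator: degradation
# follows electrode proximity (hand movement hits wrist/finger
# electrodes hardest; chest electrodes are barely disturbed).

source("analysis/00_common.R")
ensure_results()

co <- get_cohort()
mv <- run_movement_study(co, full_cfg())
print(mv)
report_studies(mv, "results")
message("wrote results/movement.csv")

worst <- mv$cells[which.max(mv$cells$error), ]
message(sprintf("largest error: %s at %s (error %.2f)",
                worst$movement, worst$placement, worst$error))
message(sprintf("chest placement worst-case error across movements: %.2f",
                max(mv$cells$error[mv$cells$placement == "chest"])))
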