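# Session study: does a two-week gap between enrollment and probe
# degrade identification, and does the effect depend on placement?
#
# Models trained on session-1 rest; probes are the session-1 rest tail
# (same session) and the first 2 minutes of session-2 rest (different
# session). The generator encodes a placement-dependent repositioning
# drift: broad chest placement drifts most, constrained finger placement
# least.

source("analysis/00_common.R")
ensure_results()

co <- get_cohort()
se <- run_session_study(co, full_cfg())
print(se)
report_studies(se, "results")
message("wrote results/session.csv")

for (pl in ecg_placements()) {
  s <- se$cells[se$cells$placement == pl, ]
  message(sprintf("%s: same-session error %.2f -> different-session error %.2f",
                  pl, s$error[s$session == "same"],
                  s$error[s$session == "different"]))
}
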