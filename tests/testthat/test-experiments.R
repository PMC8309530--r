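test_that("segmentation slices by time and preserves labels", {
  rec <- cohort_recording(small_cohort(), "S01", 1, "chest", "rest")  # 180 s
  seg <- segment_ecg(rec, 0, 120)
  expect_length(seg$samples, 60000)
  expect_identical(seg$subject_id, "S01")
  expect_identical(seg$samples, rec$samples[1:60000])
  tail_seg <- segment_ecg(rec, 120, 60)
  expect_identical(tail_seg$samples, rec$samples[60001:90000])
  expect_error(segment_ecg(rec, 150, 60), "out of range")
  expect_error(segment_ecg(rec, 0, -5), "out of range")
  # non-overlapping split of a 120 s block
  expect_identical(floor(120 / c(60, 30, 15, 10, 8, 6, 4, 2)),
                   c(2, 4, 8, 12, 15, 20, 30, 60))
})

test_that("movement study has the full factor grid and proximity ordering", {
  mv <- run_movement_study(small_cohort(), small_cfg())
  expect_identical(nrow(mv$cells), 9L)
  expect_identical(sort(unique(mv$cells$movement)),
                   sort(c("move_hands", "move_feet", "move_chest")))
  for (rep in mv$reports) expect_identical(rep$n_subjects, 8L)
  err <- function(m, p) mv$cells$error[mv$cells$movement == m &
                                         mv$cells$placement == p]
  # chest placement is robust to every movement; wrists suffer most from
  # hand movement (electrode proximity)
  expect_true(all(mv$cells$error[mv$cells$placement == "chest"] <=
                    err("move_hands", "wrists")))
  expect_gte(err("move_hands", "wrists"), err("move_feet", "wrists"))
  expect_gte(err("move_hands", "fingers"), err("move_chest", "fingers"))
})

test_that("zeroing artifact intensity removes the movement effect", {
  co0 <- no_artifact_cohort()
  cfg <- small_cfg()
  mv <- run_movement_study(co0, cfg, placements = "wrists")
  se <- run_session_study(co0, cfg, placements = "wrists")
  rest_err <- se$cells$error[se$cells$session == "same"]
  for (e in mv$cells$error) expect_lte(abs(e - rest_err), 0.15)
})

test_that("placement transfer collapses while same-placement stays accurate", {
  tr <- run_placement_transfer(small_cohort(), small_cfg())
  expect_identical(nrow(tr$cells), 2L)
  expect_identical(tr$cells$train_placement, rep("chest", 2))
  expect_setequal(tr$cells$test_placement, c("fingers", "wrists"))
  expect_true(all(tr$cells$error >= tr$baseline$error + 0.3))
})

test_that("uniform placements remove the transfer effect", {
  ap <- cohort_spec()$acq_params
  ap$placement$fingers <- ap$placement$chest
  ap$placement$wrists <- ap$placement$chest
  co <- generate_cohort(small_cohort_spec(acq_params = ap))
  tr <- run_placement_transfer(co, small_cfg())
  expect_true(all(abs(tr$cells$error - tr$baseline$error) <= 0.15))
})

test_that("same-session performance dominates different-session", {
  se <- run_session_study(small_cohort(), small_cfg())
  expect_identical(nrow(se$cells), 6L)
  for (pl in ecg_placements()) {
    same <- se$cells[se$cells$session == "same" & se$cells$placement == pl, ]
    diff <- se$cells[se$cells$session == "different" & se$cells$placement == pl, ]
    expect_gte(same$sensitivity, diff$sensitivity)
  }
  # encoded placement-drift gradient: chest degrades at least as much as
  # fingers between sessions
  drop_of <- function(pl) {
    s <- se$cells[se$cells$placement == pl, ]
    s$sensitivity[s$session == "same"] - s$sensitivity[s$session == "different"]
  }
  expect_gte(drop_of("chest"), drop_of("fingers"))
})

test_that("zeroing session drift equalizes the sessions", {
  se <- run_session_study(no_drift_cohort(), small_cfg(), placements = "chest")
  same <- se$cells$sensitivity[se$cells$session == "same"]
  diff <- se$cells$sensitivity[se$cells$session == "different"]
  expect_lte(abs(same - diff), 0.15)
})

test_that("duration sweep structure and per-segment monotonicity", {
  cfg <- small_cfg(duration_grid = c(30, 10, 2))
  ds <- run_duration_sweep(small_cohort(), cfg, variants = "different",
                           placements = "chest")
  expect_identical(nrow(ds$cells), 3L)
  expect_identical(ds$cells$n_segments, c(2L, 6L, 30L))
  f1 <- function(d) ds$cells$f1[ds$cells$duration == d]
  seg_acc <- function(d) ds$cells$segment_accuracy[ds$cells$duration == d]
  expect_gte(f1(10), f1(2))
  expect_gte(seg_acc(10), seg_acc(2))
  expect_error(run_duration_sweep(small_cohort(), small_cfg(duration_grid = 600)),
               "exceeds")
})

test_that("majority vote ties resolve by the smallest summed NRC", {
  sums <- c(S1 = 3.0, S2 = 2.5, S3 = 9)
  expect_identical(nrcid:::majority_decision(c("S1", "S2"), sums), "S2")
  expect_identical(nrcid:::majority_decision(c("S1", "S1", "S2"), sums), "S1")
})

test_that("study reports are deterministic CSV tables with provenance", {
  se <- run_session_study(small_cohort(), small_cfg(), placements = "chest")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  report_studies(se, d1)
  report_studies(se, d2)
  f1 <- file.path(d1, "session.csv")
  expect_true(file.exists(f1))
  tab <- utils::read.csv(f1)
  expect_true(all(c("Accuracy", "Error", "SEN", "SPEC", "F1score") %in% names(tab)))
  expect_identical(readLines(f1), readLines(file.path(d2, "session.csv")))
  expect_true(file.exists(file.path(d1, "provenance.json")))
  expect_error(report_studies(list(), withr::local_tempdir()), "no study")
})
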