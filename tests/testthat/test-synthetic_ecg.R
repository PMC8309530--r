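bandpower_above <- function(x, fs, f0) {
  spec <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_along(x) - 1) * fs / length(x)
  sum(spec[freqs > f0 & freqs < fs / 2])
}

count_peaks <- function(x, thresh) {
  up <- x[-1] > thresh & x[-length(x)] <= thresh
  sum(up)
}

test_that("subject sampling is deterministic and respects constraints", {
  t1 <- sample_subjects(5, seed = 42)
  t2 <- sample_subjects(5, seed = 42)
  expect_identical(t1, t2)
  for (t in t1) {
    expect_true(all(diff(t$theta) > 0))
    expect_true(all(t$b > 0))
    expect_gte(t$rr_mean, 0.5)
    expect_lte(t$rr_mean, 1.2)
  }
})

test_that("a 20-subject draw keeps all pairwise template distances above threshold", {
  ts <- sample_subjects(20, seed = 1, min_distance = 2)
  ids <- names(ts)
  for (i in 1:19)
    for (j in (i + 1):20)
      expect_gte(template_distance(ts[[ids[i]]], ts[[ids[j]]]), 2)
})

test_that("synthesis produces the requested number of samples and plausible beats", {
  t1 <- sample_subjects(1, seed = 3)[[1]]
  t1$rr_mean <- 0.8
  ctx <- acquisition_context(1, "chest", "rest")
  rec <- synthesize_recording(t1, ctx, duration = 10, fs = 500, seed = 5)
  expect_length(rec$samples, 5000)
  expect_identical(rec$placement, "chest")
  # ~12.5 beats expected at RR 0.8; count R-wave threshold crossings
  peaks <- count_peaks(rec$samples, 0.55 * max(rec$samples))
  expect_gte(peaks, 11)
  expect_lte(peaks, 14)
  expect_error(synthesize_recording(t1, ctx, duration = -1), "duration")
})

test_that("movement adds high-frequency band power at the affected placement", {
  t1 <- sample_subjects(1, seed = 8)[[1]]
  rest <- synthesize_recording(t1, acquisition_context(1, "wrists", "rest"),
                               duration = 20, seed = 13)
  move <- synthesize_recording(t1, acquisition_context(1, "wrists", "move_hands"),
                               duration = 20, seed = 13)
  expect_gt(bandpower_above(move$samples, 500, 20),
            bandpower_above(rest$samples, 500, 20))
})

test_that("artifact intensity encodes electrode proximity", {
  expect_identical(artifact_intensity("wrists", "rest"), 0)
  at_wrists <- vapply(c("move_hands", "move_feet", "move_chest"),
                      function(cd) artifact_intensity("wrists", cd), numeric(1))
  expect_gt(at_wrists["move_hands"], at_wrists["move_feet"])
  expect_gte(at_wrists["move_feet"], at_wrists["move_chest"])
  # distal pair: hand movement barely reaches the chest electrodes
  expect_lt(artifact_intensity("chest", "move_hands"),
            artifact_intensity("wrists", "move_hands"))
})

test_that("the default cohort plan follows the acquisition protocol", {
  plan <- cohort_plan(cohort_spec())
  expect_identical(nrow(plan), 300L)  # 20 x (3 x 4 + 3 x 1)
  expect_identical(sum(plan$session == 1), 240L)
  expect_true(all(plan$duration[plan$session == 1 & plan$condition == "rest"] == 600))
  expect_true(all(plan$duration[plan$condition == "move_hands"] == 120))
  expect_true(all(plan$duration[plan$session == 2] == 300))
  expect_error(cohort_spec(rest1_duration = 0), "positive")
})

test_that("cohort generation is byte-reproducible from the master seed", {
  sp <- cohort_spec(n_subjects = 2, rest1_duration = 8, move_duration = 4,
                    rest2_duration = 6, seed = 33)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$recordings, c2$recordings)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(length(c1$recordings), 30L)
})

test_that("a one-subject cohort generates but cannot feed identification", {
  sp <- cohort_spec(n_subjects = 1, rest1_duration = 8, move_duration = 4,
                    rest2_duration = 6, seed = 2)
  co <- generate_cohort(sp)
  expect_identical(length(co$recordings), 15L)
  seqs <- list(S01 = symbol_seq("AB", "AB"))
  expect_error(reference_set(seqs, k = 1), "at least 2")
})

test_that("within-subject NRC beats between-subject NRC with a wide gap", {
  co <- small_cohort()
  cfg <- small_cfg()
  refs <- train_references(co, cfg, "chest")
  ids <- sort(names(refs$models))
  within <- c(); between <- c()
  for (id in ids) {
    rec <- cohort_recording(co, id, 1, "chest", "rest")
    x <- prepare(segment_ecg(rec, cfg$train_duration, 30), prep_config())
    for (other in ids) {
      v <- nrc(x, refs$models[[other]])$value
      if (other == id) within <- c(within, v) else between <- c(between, v)
    }
  }
  expect_lt(mean(within), mean(between))
  expect_gt(mean(between) - mean(within), 3 * stats::sd(between))
})

test_that("session drift raises NRC against the session-1 model", {
  co <- small_cohort()
  cfg <- small_cfg()
  refs <- train_references(co, cfg, "chest")
  ids <- sort(names(refs$models))
  same <- c(); different <- c()
  for (id in ids) {
    r1 <- cohort_recording(co, id, 1, "chest", "rest")
    r2 <- cohort_recording(co, id, 2, "chest", "rest")
    same <- c(same, nrc(prepare(segment_ecg(r1, cfg$train_duration, 30),
                                prep_config()), refs$models[[id]])$value)
    different <- c(different, nrc(prepare(segment_ecg(r2, 0, 30),
                                          prep_config()), refs$models[[id]])$value)
  }
  expect_gt(mean(different), mean(same))
})
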