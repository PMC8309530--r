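#' Extract a contiguous segment of a recording
#'
#' Segmentation happens before quantization: each segment later gets its
#' own quantizer via [prepare()], so no quantizer state crosses segment
#' boundaries.
#'
#' @param rec a [raw_ecg()].
#' @param offset start time in seconds (>= 0).
#' @param duration segment length in seconds.
#' @return a [raw_ecg()] slice with labels preserved.
#' @export
segment_ecg <- function(rec, offset, duration) {
  stopifnot(inherits(rec, "raw_ecg"))
  n <- length(rec$samples)
  from <- round(offset * rec$fs) + 1L
  to <- round((offset + duration) * rec$fs)
  if (offset < 0 || duration <= 0 || to > n)
    stop(sprintf("segment [%g, %g) s out of range for a %.1f s recording",
                 offset, offset + duration, n / rec$fs), call. = FALSE)
  out <- rec
  out$samples <- rec$samples[from:to]
  out
}

#' Experiment configuration
#'
#' Defaults follow the acquisition-protocol studies: per-subject models
#' trained on the first 8 minutes of the session-1 rest block (the
#' remaining 2-minute tail is the same-session test block, so train and
#' test never overlap), order k = 20 single models, alpha = "auto",
#' 20-symbol alphabet, Butterworth order 8 / 40 Hz preprocessing, and a
#' test-duration grid of 60, 30, 15, 10, 8, 6, 4, 2 s.
#'
#' @param train_duration training segment length in s (default 480).
#' @param test_duration test block length in s (default 120).
#' @param k context order (default 20).
#' @param alpha smoothing spec (default `"auto"`).
#' @param alphabet_size quantizer alphabet size (default 20).
#' @param filter_order,cutoff Butterworth parameters (defaults 8, 40 Hz).
#' @param duration_grid segment durations in s for the sweep.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(train_duration = 480, test_duration = 120,
                              k = 20, alpha = "auto", alphabet_size = 20,
                              filter_order = 8, cutoff = 40,
                              duration_grid = c(60, 30, 15, 10, 8, 6, 4, 2)) {
  structure(list(train_duration = train_duration,
                 test_duration = test_duration, k = k, alpha = alpha,
                 alphabet_size = alphabet_size,
                 filter_order = filter_order, cutoff = cutoff,
                 duration_grid = duration_grid),
            class = "experiment_config")
}

prep_of <- function(cfg) prep_config(filter_order = cfg$filter_order,
                                     cutoff = cfg$cutoff,
                                     alphabet_size = cfg$alphabet_size)

#' Train per-subject reference models from a cohort
#'
#' One model per subject from the first `train_duration` seconds of the
#' given (session, placement, condition) block.
#'
#' @param cohort an `ecg_cohort`.
#' @param cfg an [experiment_config()].
#' @param placement electrode placement of the training data.
#' @param session training session (default 1).
#' @param condition training condition (default `"rest"`).
#' @return a [reference_set()].
#' @export
train_references <- function(cohort, cfg, placement, session = 1L,
                             condition = "rest") {
  key <- paste(placement, session, condition, cfg$train_duration, cfg$k,
               paste(cfg$alpha, collapse = ""), cfg$alphabet_size,
               cfg$filter_order, cfg$cutoff, sep = "|")
  if (!is.null(cohort$cache) && !is.null(cohort$cache[[key]]))
    return(cohort$cache[[key]])
  ids <- sort(unique(cohort$manifest$subject_id))
  seqs <- lapply(ids, function(id) {
    rec <- cohort_recording(cohort, id, session, placement, condition)
    prepare(segment_ecg(rec, 0, cfg$train_duration), prep_of(cfg))
  })
  names(seqs) <- ids
  refs <- reference_set(seqs, k = cfg$k, alpha = cfg$alpha)
  if (!is.null(cohort$cache)) cohort$cache[[key]] <- refs
  refs
}

# Identify every subject's test segment for one study cell; returns the
# per-subject decisions and the metrics report.
identify_cell <- function(cohort, refs, cfg, placement, session, condition,
                          offset, duration) {
  ids <- sort(names(refs$models))
  seqs <- lapply(ids, function(id) {
    rec <- cohort_recording(cohort, id, session, placement, condition)
    prepare(segment_ecg(rec, offset, duration), prep_of(cfg))
  })
  predicted <- decide_min_nrc(nrc_matrix(seqs, refs))
  list(truth = ids, predicted = unname(predicted),
       metrics = evaluate_assignments(ids, predicted))
}

metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy, error = m$error,
             sensitivity = m$sensitivity, specificity = m$specificity,
             f1 = m$f1)
}

new_study_result <- function(study, cells, reports, cohort, cfg) {
  structure(list(study = study, cells = cells, reports = reports,
                 config = cfg,
                 provenance = list(seed = cohort$spec$seed,
                                   n_subjects = cohort$spec$n_subjects,
                                   config_hash = hash_object(cfg),
                                   manifest_hash = hash_object(
                                     cohort$manifest[, c("subject_id", "session",
                                                         "placement", "condition",
                                                         "duration", "seed")]))),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s (%d cells)\n", x$study, nrow(x$cells)))
  print(x$cells, digits = 3)
  invisible(x)
}

#' Movement study
#'
#' For each placement, trains per-subject models on session-1 rest and
#' identifies each subject's movement-condition test segment, for each of
#' the three movement types. Both train and test come from session 1, so
#' the cell differences isolate the movement factor.
#'
#' @param cohort an `ecg_cohort` with session-1 movement blocks.
#' @param cfg an [experiment_config()].
#' @param placements placements to evaluate (default all in the cohort).
#' @return a `study_result` with one cell per placement x movement.
#' @export
run_movement_study <- function(cohort, cfg = experiment_config(),
                               placements = cohort$spec$placements) {
  movements <- c("move_hands", "move_feet", "move_chest")
  cells <- NULL
  reports <- list()
  for (pl in placements) {
    refs <- train_references(cohort, cfg, pl)
    for (mv in movements) {
      dur <- min(cfg$test_duration,
                 cohort$spec$move_duration)
      cell <- identify_cell(cohort, refs, cfg, pl, 1L, mv, 0, dur)
      key <- paste(mv, pl, sep = ".")
      reports[[key]] <- cell$metrics
      cells <- rbind(cells, cbind(
        data.frame(movement = mv, placement = pl),
        metrics_row(cell$metrics)))
    }
  }
  new_study_result("movement", cells, reports, cohort, cfg)
}

#' Electrode placement transfer study
#'
#' Trains on session-1 resting chest data and tests on resting segments
#' recorded simultaneously at the fingers and wrists (the same-session
#' rest tail), quantifying how identification collapses when the
#' reference and probe placements differ.
#'
#' @param cohort an `ecg_cohort` containing all three placements.
#' @param cfg an [experiment_config()].
#' @return a `study_result` with the two transfer cells
#'   (chest -> fingers, chest -> wrists); the same-placement chest control
#'   cell is attached as `$baseline`.
#' @export
run_placement_transfer <- function(cohort, cfg = experiment_config()) {
  refs <- train_references(cohort, cfg, "chest")
  cells <- NULL
  reports <- list()
  for (pl in c("fingers", "wrists")) {
    cell <- identify_cell(cohort, refs, cfg, pl, 1L, "rest",
                          cfg$train_duration, cfg$test_duration)
    key <- paste("chest", pl, sep = "->")
    reports[[key]] <- cell$metrics
    cells <- rbind(cells, cbind(
      data.frame(train_placement = "chest", test_placement = pl),
      metrics_row(cell$metrics)))
  }
  res <- new_study_result("placement_transfer", cells, reports, cohort, cfg)
  base <- identify_cell(cohort, refs, cfg, "chest", 1L, "rest",
                        cfg$train_duration, cfg$test_duration)
  res$baseline <- base$metrics
  res
}

#' Session study
#'
#' Per placement: models trained on the first 8 minutes of session-1 rest,
#' evaluated on the session-1 rest tail (same session) and on the first
#' 2 minutes of session-2 rest (different session, two weeks later).
#'
#' @param cohort an `ecg_cohort` with both sessions.
#' @param cfg an [experiment_config()].
#' @param placements placements to evaluate.
#' @return a `study_result` with one cell per session-variant x placement.
#' @export
run_session_study <- function(cohort, cfg = experiment_config(),
                              placements = cohort$spec$placements) {
  cells <- NULL
  reports <- list()
  for (pl in placements) {
    refs <- train_references(cohort, cfg, pl)
    for (variant in c("same", "different")) {
      if (variant == "same") {
        cell <- identify_cell(cohort, refs, cfg, pl, 1L, "rest",
                              cfg$train_duration, cfg$test_duration)
      } else {
        cell <- identify_cell(cohort, refs, cfg, pl, 2L, "rest",
                              0, cfg$test_duration)
      }
      key <- paste(variant, pl, sep = ".")
      reports[[key]] <- cell$metrics
      cells <- rbind(cells, cbind(
        data.frame(session = variant, placement = pl),
        metrics_row(cell$metrics)))
    }
  }
  new_study_result("session", cells, reports, cohort, cfg)
}

# Majority vote over a subject's segment decisions; ties go to the
# candidate with the smallest summed NRC over the subject's segments.
majority_decision <- function(decisions, nrc_sums) {
  tab <- table(decisions)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  top[which.min(nrc_sums[top])]
}

#' Test-segment duration sweep
#'
#' Splits each subject's 2-minute test block into non-overlapping segments
#' of each grid duration, identifies every segment (each with its own
#' quantizer), and aggregates a subject's segment decisions into one
#' decision by majority vote (ties broken by the smallest summed NRC).
#' Per-segment accuracy is reported alongside the one-decision-per-subject
#' metrics.
#'
#' @param cohort an `ecg_cohort`.
#' @param cfg an [experiment_config()]; `duration_grid` sets the sweep.
#' @param variants `"different"` (train session 1, test session 2; the
#'   realistic setting), `"same"`, or both.
#' @param placements placements to evaluate.
#' @return a `study_result`; cells carry placement, duration, variant,
#'   `n_segments`, `segment_accuracy` and the metrics columns.
#' @export
run_duration_sweep <- function(cohort, cfg = experiment_config(),
                               variants = c("different", "same"),
                               placements = cohort$spec$placements) {
  variants <- match.arg(variants, c("different", "same"), several.ok = TRUE)
  if (any(cfg$duration_grid > cfg$test_duration))
    stop("duration grid exceeds the test block length", call. = FALSE)
  cells <- NULL
  reports <- list()
  for (pl in placements) {
    refs <- train_references(cohort, cfg, pl)
    ids <- sort(names(refs$models))
    for (variant in variants) {
      session <- if (variant == "same") 1L else 2L
      base_off <- if (variant == "same") cfg$train_duration else 0
      blocks <- lapply(ids, function(id)
        segment_ecg(cohort_recording(cohort, id, session, pl, "rest"),
                    base_off, cfg$test_duration))
      names(blocks) <- ids
      for (d in cfg$duration_grid) {
        n_seg <- floor(cfg$test_duration / d)
        seqs <- list()
        for (id in ids)
          for (j in seq_len(n_seg))
            seqs[[paste(id, j)]] <- prepare(
              segment_ecg(blocks[[id]], (j - 1) * d, d), prep_of(cfg))
        sc <- nrc_matrix(seqs, refs)
        all_decisions <- decide_min_nrc(sc)
        decided <- character(length(ids))
        names(decided) <- ids
        seg_correct <- 0L
        for (i in seq_along(ids)) {
          id <- ids[i]
          rows <- (i - 1) * n_seg + seq_len(n_seg)
          decisions <- all_decisions[rows]
          seg_correct <- seg_correct + sum(decisions == id)
          decided[id] <- majority_decision(decisions, colSums(sc[rows, ,
                                                                 drop = FALSE]))
        }
        m <- evaluate_assignments(ids, unname(decided))
        key <- paste(variant, pl, d, sep = ".")
        reports[[key]] <- m
        cells <- rbind(cells, cbind(
          data.frame(session = variant, placement = pl, duration = d,
                     n_segments = as.integer(n_seg),
                     segment_accuracy = seg_correct / (n_seg * length(ids))),
          metrics_row(m)))
      }
    }
  }
  new_study_result("duration_sweep", cells, reports, cohort, cfg)
}

#' Write study results as CSV tables
#'
#' One CSV per study mirroring the movement/session table columns
#' (factor levels, Accuracy, Error, SEN, SPEC, F1score), plus
#' `duration_curve.csv` (placement, duration, F1) for the sweep, and a
#' `provenance.json` with config hash, seeds and manifest hash. Reruns
#' with the same seed are byte-identical.
#'
#' @param results list of `study_result` objects (or a single one).
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
report_studies <- function(results, dir) {
  if (inherits(results, "study_result")) results <- list(results)
  if (length(results) == 0L) stop("no study results to report", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  prov <- list()
  for (res in results) {
    stopifnot(inherits(res, "study_result"))
    tab <- res$cells
    names(tab) <- sub("^accuracy$", "Accuracy", names(tab))
    names(tab) <- sub("^error$", "Error", names(tab))
    names(tab) <- sub("^sensitivity$", "SEN", names(tab))
    names(tab) <- sub("^specificity$", "SPEC", names(tab))
    names(tab) <- sub("^f1$", "F1score", names(tab))
    p <- file.path(dir, paste0(res$study, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
    if (res$study == "duration_sweep") {
      curve <- res$cells[, c("session", "placement", "duration", "f1")]
      names(curve) <- c("session", "placement", "duration", "F1score")
      pc <- file.path(dir, "duration_curve.csv")
      utils::write.csv(curve, pc, row.names = FALSE)
      paths <- c(paths, pc)
    }
    prov[[res$study]] <- res$provenance
  }
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, pj))
}
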