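# Readers/writers and provenance shared by all modules. CSV dialect is
# pinned: UTF-8, comma separator, '.' decimal, mandatory header row.

METRICS_SCHEMA_VERSION <- "1.0"

#' Hash an R object (provenance fingerprint)
#'
#' Deterministic MD5 of the object's canonical serialization; used to
#' stamp study results with config and manifest fingerprints.
#' @param x any serializable object.
#' @return hex string.
#' @export
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(x, con, version = 2, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tmp))
}

#' Write / read a single ECG recording
#'
#' A recording is stored as a CSV (columns `sample_index`, `voltage`) plus
#' a JSON sidecar holding `{subject_id, session, placement, condition,
#' fs}`. The pair round-trips losslessly (voltages at full double
#' precision).
#'
#' @param rec a [raw_ecg()].
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the [raw_ecg()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_ecg"))
  df <- data.frame(sample_index = seq_along(rec$samples) - 1L,
                   voltage = format(rec$samples, digits = 17, trim = TRUE,
                                    scientific = FALSE))
  data.table::fwrite(df, path, quote = FALSE)
  side <- list(subject_id = rec$subject_id, session = rec$session,
               placement = rec$placement, condition = rec$condition,
               fs = rec$fs)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sidecar %s", sidecar), call. = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("subject_id", "session", "placement", "condition", "fs"))
    if (is.null(side[[field]]))
      stop(sprintf("sidecar %s lacks required field '%s'", sidecar, field),
           call. = FALSE)
  df <- data.table::fread(path)
  if (!all(c("sample_index", "voltage") %in% names(df)))
    stop("recording CSV must have columns sample_index, voltage",
         call. = FALSE)
  df$voltage <- as.numeric(df$voltage)
  raw_ecg(df$voltage, fs = side$fs, subject_id = side$subject_id,
          session = side$session, placement = side$placement,
          condition = side$condition)
}

#' Write a cohort to disk
#'
#' One CSV + JSON sidecar per recording plus a `manifest.csv` listing
#' every file with its labels, duration and an MD5 checksum, so any
#' on-disk mutation is detectable.
#'
#' @param cohort an `ecg_cohort`.
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- cohort$manifest
  plan$path <- file.path(dir, paste0(plan$key, ".csv"))
  for (i in seq_len(nrow(plan)))
    write_recording(cohort$recordings[[plan$key[i]]], plan$path[i])
  plan$md5 <- unname(tools::md5sum(plan$path))
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(plan[, c("path", "subject_id", "session", "placement",
                            "condition", "fs", "duration", "md5")],
                   mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort manifest and verify checksums
#'
#' @param dir directory written by [write_cohort()].
#' @return the manifest data.frame.
#' @export
read_manifest <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  man <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  now <- unname(tools::md5sum(man$path))
  bad <- man$path[is.na(now) | now != man$md5]
  if (length(bad))
    stop(sprintf("checksum mismatch or missing file: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  man
}

#' Write / read a metrics report as JSON
#'
#' Lossless round-trip of all metric fields including the confusion
#' matrix; the file carries a schema-version field which is checked on
#' read.
#'
#' @param report a `metrics_report`.
#' @param path JSON path.
#' @return `write_metrics` returns `path` invisibly; `read_metrics`
#'   returns the `metrics_report`.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(schema_version = METRICS_SCHEMA_VERSION,
              n_subjects = report$n_subjects,
              accuracy = report$accuracy, error = report$error,
              sensitivity = report$sensitivity,
              specificity = report$specificity, f1 = report$f1,
              classes = rownames(report$confusion),
              confusion = unclass(report$confusion))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) ||
      obj$schema_version != METRICS_SCHEMA_VERSION)
    stop("unsupported or missing metrics schema version", call. = FALSE)
  conf <- matrix(as.integer(obj$confusion), nrow = length(obj$classes),
                 dimnames = list(truth = obj$classes,
                                 predicted = obj$classes))
  structure(list(n_subjects = obj$n_subjects, accuracy = obj$accuracy,
                 error = obj$error, sensitivity = obj$sensitivity,
                 specificity = obj$specificity, f1 = obj$f1,
                 confusion = conf),
            class = "metrics_report")
}

#' Write / read a symbol sequence as plain text
#'
#' One sequence per file: a header line `#alphabet=<chars>` followed by
#' the sequence on a single line.
#'
#' @param seq a [symbol_seq()].
#' @param path output file.
#' @return `write_symbol_seq` returns `path` invisibly; `read_symbol_seq`
#'   returns the [symbol_seq()].
#' @export
write_symbol_seq <- function(seq, path) {
  stopifnot(inherits(seq, "symbol_seq"))
  writeLines(c(paste0("#alphabet=", seq$alphabet), seq$symbols), path)
  invisible(path)
}

#' @rdname write_symbol_seq
#' @export
read_symbol_seq <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#alphabet="))
    stop("not a symbol sequence file", call. = FALSE)
  symbol_seq(lines[2], sub("^#alphabet=", "", lines[1]))
}
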