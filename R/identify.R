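#' Normalized Relative Compression of a segment against a model
#'
#' `NRC(x||y) = C(x||y) / |x|` in the binary-string convention. Over an
#' alphabet of size |A| the raw bits-per-symbol value ranges up to
#' `log2 |A|`, so the default `value` is additionally divided by
#' `log2 |A|`, mapping an incompressible segment (uniform coding) to 1.
#' The raw convention (`raw`, division by |x| only) is also returned;
#' identification by argmin is invariant to the choice of normalizer.
#'
#' @param x a non-empty [symbol_seq()].
#' @param model a trained [fcm_train()] model.
#' @return list with `value` (bits per symbol over the alphabet maximum),
#'   `raw` (bits per symbol), and `bits`.
#' @export
nrc <- function(x, model) {
  stopifnot(inherits(x, "symbol_seq"))
  if (nchar(x$symbols) == 0L)
    stop("cannot score an empty sequence", call. = FALSE)
  cl <- code_length(x, model)
  A <- nchar(model$alphabet)
  list(value = cl$bits / (cl$n_symbols * log2(A)),
       raw = cl$bits / cl$n_symbols,
       bits = cl$bits)
}

#' Build a reference set of per-subject models
#'
#' Trains one finite-context model per subject from that subject's training
#' symbol sequence. All models share `k`, the alphabet and the alpha
#' specification (alpha = "auto" resolves per subject on its own training
#' sequence).
#'
#' @param seqs named list of [symbol_seq()], one per subject; at least 2.
#' @param k context order (default 20).
#' @param alpha smoothing specification (default `"auto"`).
#' @return object of class `reference_set`.
#' @export
reference_set <- function(seqs, k = 20, alpha = "auto") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("seqs must be a uniquely named list keyed by subject_id", call. = FALSE)
  if (length(seqs) < 2L)
    stop("a reference set needs at least 2 subjects", call. = FALSE)
  alphabets <- vapply(seqs, function(s) s$alphabet, "")
  if (length(unique(alphabets)) != 1L)
    stop("all reference sequences must share an alphabet", call. = FALSE)
  models <- lapply(seqs, fcm_train, k = k, alpha = alpha)
  structure(list(models = models, k = k, alpha = alpha,
                 alphabet = alphabets[[1]]),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d subjects, k=%d, |A|=%d\n",
              length(x$models), x$k, nchar(x$alphabet)))
  invisible(x)
}

#' Score many segments against a reference set
#'
#' NRC of every segment under every subject model, computed in one pass
#' per model.
#'
#' @param seqs list of [symbol_seq()] over the reference alphabet.
#' @param refs a [reference_set()].
#' @return numeric matrix, rows = segments, columns = subjects (sorted
#'   ids), of normalized NRC values.
#' @export
nrc_matrix <- function(seqs, refs) {
  stopifnot(inherits(refs, "reference_set"))
  ids <- sort(names(refs$models))
  strs <- vapply(seqs, function(s) s$symbols, "")
  lens <- nchar(strs)
  if (any(lens == 0L)) stop("cannot score an empty sequence", call. = FALSE)
  A <- nchar(refs$alphabet)
  out <- vapply(ids, function(id) {
    m <- refs$models[[id]]
    fcm_bits_batch_cpp(m$ptr, strs, m$alpha) / (lens * log2(A))
  }, numeric(length(seqs)))
  matrix(out, nrow = length(seqs), dimnames = list(NULL, ids))
}

# argmin decision per row of an NRC matrix; exact ties go to the
# lexicographically smallest subject id with a warning.
decide_min_nrc <- function(scores) {
  ids <- colnames(scores)
  apply(scores, 1L, function(row) {
    best <- ids[row == min(row)]
    if (length(best) > 1L)
      warning(sprintf("NRC tie between {%s}; choosing smallest subject id",
                      paste(best, collapse = ", ")), call. = FALSE)
    best[1L]
  })
}

#' Identify the subject of a test segment
#'
#' Scores the segment against every reference model and attributes it to
#' the subject with the minimum NRC. Exact ties are broken toward the
#' lexicographically smallest subject id, with a warning. The decision is
#' invariant to the NRC normalizer: the argmin over models of
#' `C(x||.)/const` is the argmin of `C(x||.)`.
#'
#' @param x a [symbol_seq()].
#' @param refs a [reference_set()].
#' @return list with `subject` (the decision) and `scores` (data.frame of
#'   subject_id, nrc, rank).
#' @export
identify_subject <- function(x, refs) {
  stopifnot(inherits(x, "symbol_seq"))
  sc <- nrc_matrix(list(x), refs)
  scores <- data.frame(subject_id = colnames(sc), nrc = as.numeric(sc[1L, ]),
                       rank = rank(sc[1L, ], ties.method = "min"),
                       stringsAsFactors = FALSE)
  list(subject = decide_min_nrc(sc)[[1L]], scores = scores)
}

#' Identification metrics from one decision per subject
#'
#' Builds the N-class confusion matrix (one decision per true subject) and
#' derives the macro one-vs-all metrics used throughout:
#' sensitivity = correct/N, error = 1 - sensitivity,
#' accuracy = mean over classes of (TP_c + TN_c)/N,
#' specificity = mean over classes of TN_c/(N-1),
#' F1 = macro mean of per-class 2 TP_c / (2 TP_c + FP_c + FN_c).
#'
#' @param truth character vector of true subject ids.
#' @param predicted character vector of decisions, parallel to `truth`.
#' @return object of class `metrics_report` with fields `n_subjects`,
#'   `accuracy`, `error`, `sensitivity`, `specificity`, `f1` and the
#'   integer `confusion` matrix (rows = truth, cols = predicted).
#' @export
evaluate_assignments <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must be parallel", call. = FALSE)
  if (anyDuplicated(truth))
    stop("this evaluator expects exactly one decision per subject", call. = FALSE)
  classes <- sort(unique(c(truth, predicted)))
  n <- length(truth)
  conf <- table(factor(truth, levels = classes),
                factor(predicted, levels = classes))
  conf <- matrix(as.integer(conf), nrow = length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- sum(conf) - tp - fp - fn
  sen <- sum(tp) / n
  metrics <- list(
    n_subjects = n,
    accuracy = mean((tp + tn) / n),
    error = 1 - sen,
    sensitivity = sen,
    specificity = mean(tn / (n - 1)),
    f1 = mean(2 * tp / (2 * tp + fp + fn)),
    confusion = conf)
  structure(metrics, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> N=%d  accuracy %.2f  error %.2f  SEN %.2f  SPEC %.2f  F1 %.2f\n",
    x$n_subjects, x$accuracy, x$error, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}
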