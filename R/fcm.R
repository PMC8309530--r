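#' Train a finite-context model
#'
#' Accumulates order-`k` conditional symbol counts over the sequence. The
#' sequence is treated as circular: the context of each of the first `k`
#' symbols wraps to the end of the sequence, so the total count mass equals
#' the sequence length exactly.
#'
#' @param seq a [symbol_seq()].
#' @param k context order (>= 1). Default 20.
#' @param alpha smoothing parameter: a positive number, or `"auto"` to pick
#'   the value from a fixed candidate grid that minimises the model's
#'   self-code-length (see [resolve_alpha()]).
#' @return an object of class `fcm` holding the sparse count table, `k`,
#'   the alphabet, the resolved numeric `alpha` and the original request
#'   `alpha_spec`.
#' @export
fcm_train <- function(seq, k = 20, alpha = "auto") {
  stopifnot(inherits(seq, "symbol_seq"))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  if (nchar(seq$symbols) < 1L)
    stop("cannot train on an empty sequence", call. = FALSE)
  ptr <- fcm_train_cpp(seq$symbols, k, seq$alphabet)
  model <- structure(
    list(ptr = ptr, k = k, alphabet = seq$alphabet,
         alpha = NA_real_, alpha_spec = alpha,
         n_train = nchar(seq$symbols)),
    class = "fcm")
  model$alpha <- resolve_alpha(alpha, model = model, y = seq)
  model
}

#' @export
print.fcm <- function(x, ...) {
  cat(sprintf("<fcm> k=%d, |A|=%d, alpha=%g (%s), trained on %d symbols\n",
              x$k, nchar(x$alphabet), x$alpha,
              if (identical(x$alpha_spec, "auto")) "auto" else "fixed",
              x$n_train))
  invisible(x)
}

#' An empty finite-context model
#'
#' A model with no accumulated counts: every context is unseen, so every
#' symbol probability is `1/|A|` and coding any sequence of length n costs
#' exactly `n * log2(|A|)` bits.
#'
#' @param k context order.
#' @param alphabet single string of alphabet characters.
#' @param alpha smoothing parameter (any positive number; the coding cost
#'   of an empty model does not depend on it).
#' @return an `fcm` with zero count mass.
#' @export
fcm_empty <- function(k = 20, alphabet = ecg_alphabet(20), alpha = 1) {
  k <- as.integer(k)
  A <- nchar(alphabet)
  ptr <- fcm_import_cpp(character(0), matrix(integer(0), 0, A), k, alphabet, 0)
  structure(list(ptr = ptr, k = k, alphabet = alphabet,
                 alpha = as.numeric(alpha), alpha_spec = alpha, n_train = 0L),
            class = "fcm")
}

#' Candidate smoothing values for alpha = "auto"
#' @return decreasing numeric grid.
#' @export
alpha_grid <- function() c(1, 0.5, 0.25, 0.1, 0.05, 0.02, 0.01)

#' Resolve the smoothing parameter
#'
#' A numeric specification is returned unchanged. `"auto"` evaluates every
#' candidate in [alpha_grid()] and returns the one minimising the
#' self-code-length of the training sequence under the trained model
#' (ties broken toward the larger alpha). This is a deterministic,
#' documented selection rule; any numeric alpha overrides it.
#'
#' @param spec `"auto"` or a positive number.
#' @param y training [symbol_seq()] (required for `"auto"` unless `model`
#'   was trained on it and `y` is supplied alongside).
#' @param k context order used when `model` is not supplied.
#' @param model optionally, an already-trained `fcm` on `y` (avoids
#'   retraining).
#' @return positive numeric alpha.
#' @export
resolve_alpha <- function(spec, y = NULL, k = NULL, model = NULL) {
  if (is.numeric(spec)) {
    if (length(spec) != 1L || !is.finite(spec) || spec <= 0)
      stop("numeric alpha must be a positive scalar", call. = FALSE)
    return(as.numeric(spec))
  }
  if (!identical(spec, "auto"))
    stop("alpha must be a positive number or 'auto'", call. = FALSE)
  if (is.null(y))
    stop("alpha = 'auto' needs the training sequence", call. = FALSE)
  if (is.null(model))
    model <- fcm_train(y, k = k, alpha = 1)  # counts only; alpha irrelevant
  lk <- fcm_lookup_cpp(model$ptr, y$symbols)
  A <- nchar(model$alphabet)
  bits <- vapply(alpha_grid(), function(a)
    sum(-log2((lk$v + a) / (lk$tot + a * A))), numeric(1))
  alpha_grid()[which.min(bits)]  # first minimum = largest alpha on ties
}

#' Smoothed conditional symbol probability
#'
#' Additive-smoothing estimate
#' `P(s | ctx) = (v(s|ctx) + alpha) / (sum_a v(a|ctx) + alpha |A|)`,
#' balancing the maximum-likelihood estimate against a uniform
#' distribution. An unseen context yields `1/|A|` for every symbol.
#'
#' @param model a trained `fcm`.
#' @param context string of length `k`.
#' @param s single symbol.
#' @param alpha optional override of the model's resolved alpha.
#' @return probability strictly inside (0, 1).
#' @export
fcm_prob <- function(model, context, s, alpha = model$alpha) {
  stopifnot(inherits(model, "fcm"))
  if (!is.numeric(alpha) || !is.finite(alpha) || alpha <= 0)
    stop("alpha is not resolved to a positive number", call. = FALSE)
  A <- nchar(model$alphabet)
  cnt <- fcm_context_counts_cpp(model$ptr, context)
  i <- regexpr(s, model$alphabet, fixed = TRUE)
  if (i < 0) stop("symbol not in alphabet", call. = FALSE)
  (cnt[i] + alpha) / (cnt[A + 1] + alpha * A)
}

#' Total code length of a sequence under a frozen model
#'
#' The number of bits an order-`k` model with frozen counts needs to encode
#' `x`: `sum_i -log2 P(x_i | x_{i-k}^{i-1})`, with the contexts of the
#' first `k` symbols wrapping circularly within `x`. The model is never
#' updated while coding (exclusive / static model), so this is the relative
#' compression C(x || training data).
#'
#' @param x a [symbol_seq()] over the model's alphabet.
#' @param model a trained `fcm`.
#' @param alpha optional override of the model's resolved alpha.
#' @return list with `bits` (nonnegative) and `n_symbols`.
#' @export
code_length <- function(x, model, alpha = model$alpha) {
  stopifnot(inherits(x, "symbol_seq"), inherits(model, "fcm"))
  if (!identical(x$alphabet, model$alphabet))
    stop("alphabet mismatch between sequence and model", call. = FALSE)
  if (!is.numeric(alpha) || !is.finite(alpha) || alpha <= 0)
    stop("alpha is not resolved to a positive number", call. = FALSE)
  lk <- fcm_lookup_cpp(model$ptr, x$symbols)
  A <- nchar(model$alphabet)
  bits <- sum(-log2((lk$v + alpha) / (lk$tot + alpha * A)))
  list(bits = bits, n_symbols = nchar(x$symbols))
}

#' Relative compression C(x||y)
#'
#' Bits needed to encode `x` with a static model built exclusively from
#' `y`: `code_length(x, fcm_train(y, k, alpha))`.
#'
#' @param x,y [symbol_seq()] objects over a shared alphabet.
#' @param k context order.
#' @param alpha smoothing (number or `"auto"`, resolved on `y`).
#' @return list with `bits` and `n_symbols` (of `x`).
#' @export
relative_compression <- function(x, y, k = 20, alpha = "auto") {
  if (!identical(x$alphabet, y$alphabet))
    stop("x and y must share an alphabet", call. = FALSE)
  code_length(x, fcm_train(y, k = k, alpha = alpha))
}

#' Serialize / deserialize a finite-context model
#'
#' Flat TSV of (context, per-symbol counts) preceded by a header line with
#' `k`, the alphabet, alpha and the training length. Round-trips are
#' lossless; contexts are written in sorted order so output is
#' byte-deterministic.
#'
#' @param model a trained `fcm`.
#' @param path output file.
#' @return `write_fcm` returns `path` invisibly; `read_fcm` returns the
#'   reconstructed `fcm`.
#' @export
write_fcm <- function(model, path) {
  stopifnot(inherits(model, "fcm"))
  ex <- fcm_export_cpp(model$ptr)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("#fcm\tk=%d\talphabet=%s\talpha=%s\talpha_spec=%s\tn_train=%d",
                 model$k, model$alphabet,
                 format(model$alpha, digits = 17),
                 as.character(model$alpha_spec), model$n_train)
  writeLines(hdr, con)
  if (length(ex$context)) {
    rows <- paste(ex$context,
                  apply(ex$counts, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_fcm
#' @export
read_fcm <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#fcm"))
    stop("not an fcm model file", call. = FALSE)
  hdr <- strsplit(lines[1], "\t")[[1]][-1]
  kv <- strsplit(hdr, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  k <- as.integer(vals[["k"]])
  alphabet <- vals[["alphabet"]]
  A <- nchar(alphabet)
  body <- lines[-1]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    contexts <- vapply(parts, `[`, "", 1L)
    counts <- t(vapply(parts, function(p) as.integer(p[-1]), integer(A)))
  } else {
    contexts <- character(0)
    counts <- matrix(integer(0), 0, A)
  }
  ptr <- fcm_import_cpp(contexts, counts, k, alphabet,
                        as.numeric(vals[["n_train"]]))
  spec <- vals[["alpha_spec"]]
  structure(
    list(ptr = ptr, k = k, alphabet = alphabet,
         alpha = as.numeric(vals[["alpha"]]),
         alpha_spec = if (identical(spec, "auto")) "auto" else as.numeric(spec),
         n_train = as.integer(as.numeric(vals[["n_train"]]))),
    class = "fcm")
}
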