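#' Construct a raw ECG recording
#'
#' Container for a single-lead sampled voltage series together with its
#' acquisition labels: subject, session, electrode placement and condition.
#'
#' @param samples numeric vector of voltages (arbitrary units); must be
#'   non-empty and finite.
#' @param fs sampling rate in Hz (default 500).
#' @param subject_id subject label.
#' @param session session label, 1 or 2.
#' @param placement electrode placement: one of `"fingers"`, `"wrists"`,
#'   `"chest"`.
#' @param condition acquisition condition: one of `"rest"`, `"move_hands"`,
#'   `"move_feet"`, `"move_chest"`.
#' @return an object of class `raw_ecg`.
#' @export
raw_ecg <- function(samples, fs = 500, subject_id = "S01", session = 1L,
                    placement = "chest", condition = "rest") {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("samples must all be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  session <- as.integer(session)
  if (!session %in% c(1L, 2L))
    stop("session must be 1 or 2", call. = FALSE)
  placement <- match.arg(placement, ecg_placements())
  condition <- match.arg(condition, ecg_conditions())
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         subject_id = as.character(subject_id),
         session = session, placement = placement, condition = condition),
    class = "raw_ecg")
}

#' @export
print.raw_ecg <- function(x, ...) {
  cat(sprintf("<raw_ecg> subject %s, session %d, %s, %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session, x$placement, x$condition,
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Closed vocabularies for acquisition labels
#'
#' @return character vector of admissible labels.
#' @export
ecg_placements <- function() c("fingers", "wrists", "chest")

#' @rdname ecg_placements
#' @export
ecg_conditions <- function() c("rest", "move_hands", "move_feet", "move_chest")

#' Symbol alphabet for quantized ECG
#'
#' Symbols are rendered as capital letters `A..Z`; alphabets larger than 26
#' extend with lowercase letters and digits.
#'
#' @param n alphabet size (2..62).
#' @return single string whose characters are the ordered alphabet.
#' @export
ecg_alphabet <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n < 2 || n > length(pool))
    stop(sprintf("alphabet size must be in [2, %d]", length(pool)), call. = FALSE)
  paste(pool[seq_len(n)], collapse = "")
}

#' Construct a symbol sequence
#'
#' A string over a finite single-character alphabet; the unit of
#' compression.
#'
#' @param symbols single string of symbols.
#' @param alphabet single string whose characters form the ordered alphabet.
#' @return an object of class `symbol_seq`.
#' @export
symbol_seq <- function(symbols, alphabet) {
  stopifnot(is.character(symbols), length(symbols) == 1L,
            is.character(alphabet), length(alphabet) == 1L)
  if (nchar(symbols) > 0L) {
    bad <- setdiff(strsplit(symbols, "")[[1]], strsplit(alphabet, "")[[1]])
    if (length(bad))
      stop(sprintf("symbols outside alphabet: %s",
                   paste(unique(bad), collapse = "")), call. = FALSE)
  }
  structure(list(symbols = symbols, alphabet = alphabet), class = "symbol_seq")
}

#' @export
print.symbol_seq <- function(x, ...) {
  s <- x$symbols
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 60), "...") else s
  cat(sprintf("<symbol_seq> %d symbols over |A|=%d: %s\n",
              nchar(s), nchar(x$alphabet), shown))
  invisible(x)
}

#' @export
length.symbol_seq <- function(x) nchar(x$symbols)
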