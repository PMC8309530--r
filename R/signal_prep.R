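#' Zero-phase Butterworth low-pass filter
#'
#' Filters the recording forward and backward (zero-phase) with a
#' Butterworth low-pass design, so ECG morphology is not phase-distorted.
#' The effective magnitude response is the squared one-pass response.
#'
#' @param ecg a [raw_ecg()].
#' @param order filter order (default 8).
#' @param cutoff cutoff frequency in Hz (default 40); must be below Nyquist.
#' @return a `raw_ecg` of the same length with labels preserved.
#' @export
lowpass_filter <- function(ecg, order = 8, cutoff = 40) {
  stopifnot(inherits(ecg, "raw_ecg"))
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  if (cutoff <= 0 || cutoff >= ecg$fs / 2)
    stop("cutoff must lie at or above 0 and below the Nyquist frequency",
         call. = FALSE)
  bt <- signal::butter(order, cutoff / (ecg$fs / 2), type = "low")
  out <- ecg
  out$samples <- zero_phase_filter(bt, ecg$samples)
  out
}

# Forward-backward filtering with odd (antisymmetric) edge extension long
# enough for the filter's zero-state transient to die inside the padding;
# the pad length comes from the slowest pole of the design, so a constant
# passes through unchanged to ~1e-13 and edges are not distorted.
zero_phase_filter <- function(bt, x) {
  n <- length(x)
  r <- max(Mod(polyroot(rev(bt$a))))
  pad <- max(50, ceiling(log(1e-13) / log(min(r, 0.999))))
  pad <- min(n - 1, pad)
  front <- 2 * x[1] - x[seq(pad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- as.numeric(signal::filtfilt(bt, c(front, x, back)))
  y[(pad + 1):(pad + n)]
}

#' First differences of a recording
#'
#' Consecutive differences of the (filtered) voltage series; this is the
#' quantizer input and suppresses baseline wander.
#'
#' @param ecg a [raw_ecg()] with at least 2 samples.
#' @return numeric vector of length `n - 1`.
#' @export
diff_series <- function(ecg) {
  stopifnot(inherits(ecg, "raw_ecg"))
  if (length(ecg$samples) < 2L)
    stop("need at least 2 samples to difference", call. = FALSE)
  diff(ecg$samples)
}

#' Fit an equal-frequency quantizer
#'
#' Learns `alphabet_size - 1` breakpoints as empirical quantiles of the
#' series at probabilities j/|A| (linear-interpolation quantiles), so each
#' output symbol covers approximately equal sample mass: regions of the
#' difference distribution with higher probability get narrower intervals.
#'
#' @param values numeric series (typically a difference series).
#' @param alphabet_size number of symbols |A| (default 20).
#' @param allow_degenerate if `TRUE`, coincident quantiles on a (near-)
#'   degenerate distribution are collapsed with a warning instead of
#'   raising an error.
#' @return object of class `quantizer` with fields `breakpoints` (strictly
#'   increasing, length |A|-1) and `alphabet`.
#' @export
fit_quantizer <- function(values, alphabet_size = 20, allow_degenerate = FALSE) {
  if (alphabet_size < 2)
    stop("alphabet_size must be >= 2", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) < alphabet_size)
    stop("series shorter than alphabet_size", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must all be finite", call. = FALSE)
  probs <- seq_len(alphabet_size - 1) / alphabet_size
  bp <- unname(quantile(values, probs = probs, type = 7))
  if (anyDuplicated(bp)) {
    if (!allow_degenerate)
      stop("degenerate distribution: coincident quantile breakpoints; ",
           "pass allow_degenerate = TRUE to collapse them", call. = FALSE)
    warning("collapsing coincident quantile breakpoints; effective alphabet shrinks",
            call. = FALSE)
    bp <- unique(bp)
  }
  structure(list(breakpoints = bp,
                 alphabet = ecg_alphabet(length(bp) + 1L)),
            class = "quantizer")
}

#' @export
print.quantizer <- function(x, ...) {
  cat(sprintf("<quantizer> |A|=%d, breakpoints [%.4g .. %.4g]\n",
              nchar(x$alphabet), min(x$breakpoints), max(x$breakpoints)))
  invisible(x)
}

#' Quantize a real series into symbols
#'
#' Intervals are half-open `[b_{j-1}, b_j)` with the last interval closed by
#' +Inf; a value equal to a breakpoint falls in the upper interval. Every
#' real value maps to some symbol.
#'
#' @param values numeric series.
#' @param quantizer a fitted [fit_quantizer()] model.
#' @return a [symbol_seq()] of the same length as `values`.
#' @export
quantize <- function(values, quantizer) {
  stopifnot(inherits(quantizer, "quantizer"))
  idx <- findInterval(values, quantizer$breakpoints) + 1L
  syms <- strsplit(quantizer$alphabet, "")[[1]][idx]
  symbol_seq(paste(syms, collapse = ""), quantizer$alphabet)
}

#' Preprocessing configuration
#'
#' @param filter_order Butterworth order (default 8).
#' @param cutoff low-pass cutoff in Hz (default 40).
#' @param alphabet_size quantizer alphabet size (default 20).
#' @param filter apply the low-pass filter before differencing (default TRUE).
#' @return a list of class `prep_config`.
#' @export
prep_config <- function(filter_order = 8, cutoff = 40, alphabet_size = 20,
                        filter = TRUE) {
  structure(list(filter_order = filter_order, cutoff = cutoff,
                 alphabet_size = alphabet_size, filter = filter),
            class = "prep_config")
}

#' Convert a recording to a symbol sequence
#'
#' Composition filter -> difference -> fit quantizer -> quantize. The
#' quantizer is fit on this recording's own difference series, never on any
#' other recording, so training and test data never share quantizer state
#' (no leakage). Consequently the output is invariant to positive amplitude
#' rescaling of the input.
#'
#' @param ecg a [raw_ecg()].
#' @param config a [prep_config()].
#' @param allow_degenerate passed to [fit_quantizer()].
#' @return a [symbol_seq()] of length `n - 1`.
#' @export
prepare <- function(ecg, config = prep_config(), allow_degenerate = FALSE) {
  stopifnot(inherits(ecg, "raw_ecg"), inherits(config, "prep_config"))
  if (diff(range(ecg$samples)) == 0)
    stop("degenerate distribution: constant recording has no quantizable ",
         "variation", call. = FALSE)
  if (isTRUE(config$filter))
    ecg <- lowpass_filter(ecg, order = config$filter_order, cutoff = config$cutoff)
  d <- diff_series(ecg)
  q <- fit_quantizer(d, alphabet_size = config$alphabet_size,
                     allow_degenerate = allow_degenerate)
  quantize(d, q)
}
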