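# Independent naive oracles for the compression core. These deliberately
# recount contexts from scratch at every position instead of using any
# incremental table, so they share no code path with the package
# implementation.

# Circular context of length k preceding position i (1-based) in string s.
naive_context <- function(chars, i, k) {
  n <- length(chars)
  idx <- ((i - 1 - k):(i - 2)) %% n + 1
  paste(chars[idx], collapse = "")
}

# Total bits to code x against a static model built from y, recounting
# (context, symbol) occurrences in y independently for every position of x.
naive_code_length <- function(x, y, k, alpha, alphabet) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  A <- nchar(alphabet)
  m <- length(ys)
  yctx <- vapply(seq_len(m), function(j) naive_context(ys, j, k), "")
  terms <- numeric(length(xs))
  for (i in seq_along(xs)) {
    ctx <- naive_context(xs, i, k)
    v <- sum(yctx == ctx & ys == xs[i])
    tot <- sum(yctx == ctx)
    terms[i] <- -log2((v + alpha) / (tot + alpha * A))
  }
  sum(terms)
}

# Naive circular (context, symbol) count table of a sequence, as a named
# vector "ctx|s" -> count.
naive_train_counts <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  keys <- vapply(seq_along(chars), function(i)
    paste(naive_context(chars, i, k), chars[i], sep = "|"), "")
  table(keys)
}

# Order-1 Markov chain sampler over a single-character alphabet; P is the
# row-stochastic transition matrix.
markov_seq <- function(n, P, alphabet, seed) {
  stopifnot(nrow(P) == nchar(alphabet))
  chars <- strsplit(alphabet, "")[[1]]
  withr::with_seed(seed, {
    states <- integer(n)
    states[1] <- sample.int(length(chars), 1)
    for (i in 2:n)
      states[i] <- sample.int(length(chars), 1, prob = P[states[i - 1], ])
    symbol_seq(paste(chars[states], collapse = ""), alphabet)
  })
}

# A synthetic ECG-like recording for unit tests (not the cohort generator):
# deterministic sinusoid mix plus seeded noise.
toy_ecg <- function(n = 5000, fs = 500, seed = 1, noise = 0.05, ...) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    x <- sin(2 * pi * 1.2 * t) + 0.3 * sin(2 * pi * 7 * t) +
      noise * rnorm(n)
    raw_ecg(x, fs = fs, ...)
  })
}
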