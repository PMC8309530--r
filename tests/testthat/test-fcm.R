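test_that("circular training counts match hand enumeration", {
  m <- fcm_train(symbol_seq("AAB", "AB"), k = 1, alpha = 1)
  ctxA <- nrcid:::fcm_context_counts_cpp(m$ptr, "A")
  ctxB <- nrcid:::fcm_context_counts_cpp(m$ptr, "B")
  # contexts: pos1 A|B (wrap), pos2 A|A, pos3 B|A
  expect_equal(ctxA, c(1, 1, 2))  # v(A|A), v(B|A), total
  expect_equal(ctxB, c(1, 0, 1))  # v(A|B) from the wrap-around
  expect_equal(nrcid:::fcm_mass_cpp(m$ptr), 3)

  m2 <- fcm_train(symbol_seq("AAAA", "AB"), k = 2, alpha = 1)
  expect_equal(nrcid:::fcm_context_counts_cpp(m2$ptr, "AA"), c(4, 0, 4))
})

test_that("count mass equals sequence length and matches a naive recount", {
  alpha_chars <- "ABCD"
  for (case in 1:20) {
    n <- withr::with_seed(100 + case, sample(5:80, 1))
    k <- withr::with_seed(200 + case, sample(1:3, 1))
    s <- withr::with_seed(300 + case,
      paste(sample(strsplit(alpha_chars, "")[[1]], n, TRUE), collapse = ""))
    m <- fcm_train(symbol_seq(s, alpha_chars), k = k, alpha = 0.5)
    expect_equal(nrcid:::fcm_mass_cpp(m$ptr), n)
    naive <- naive_train_counts(s, k)
    ex <- nrcid:::fcm_export_cpp(m$ptr)
    for (key in names(naive)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      got <- nrcid:::fcm_context_counts_cpp(m$ptr, parts[1])
      sym_idx <- regexpr(parts[2], alpha_chars, fixed = TRUE)
      expect_equal(got[sym_idx], unname(as.numeric(naive[key])))
    }
  }
})

test_that("smoothed probabilities follow the additive estimator", {
  m <- fcm_train(symbol_seq("AAB", "AB"), k = 1, alpha = 1)
  expect_equal(fcm_prob(m, "A", "A"), 0.5)  # (1+1)/(2+2)
  expect_equal(fcm_prob(m, "B", "B"), (0 + 1) / (1 + 2))

  # unseen context is uniform for any alpha
  m4 <- fcm_train(symbol_seq("ABAB", "ABCD"), k = 2, alpha = 1)
  for (a in c(0.01, 0.5, 7))
    expect_equal(fcm_prob(m4, "CD", "A", alpha = a), 0.25)

  # growing alpha pulls a seen context monotonically toward uniform
  p <- vapply(c(0.1, 1, 10, 100, 1e4), function(a)
    fcm_prob(m, "A", "A", alpha = a), numeric(1))
  expect_true(all(diff(abs(p - 0.5)) <= 0))
})

test_that("per-context probabilities are normalized", {
  s <- withr::with_seed(42, paste(sample(LETTERS[1:4], 300, TRUE), collapse = ""))
  m <- fcm_train(symbol_seq(s, "ABCD"), k = 2, alpha = 0.05)
  ex <- nrcid:::fcm_export_cpp(m$ptr)
  for (ctx in ex$context[1:10]) {
    total <- sum(vapply(c("A", "B", "C", "D"), function(sym)
      fcm_prob(m, ctx, sym), numeric(1)))
    expect_lt(abs(total - 1), 1e-12)
  }
})

test_that("code length matches the hand-computed circular example", {
  s <- symbol_seq("AAB", "AB")
  m <- fcm_train(s, k = 1, alpha = 1)
  expected <- -log2(2 / 3) - log2(1 / 2) - log2(1 / 2)  # ~2.585 bits
  expect_equal(code_length(s, m)$bits, expected, tolerance = 1e-12)
})

test_that("an empty model codes at exactly log2|A| bits per symbol", {
  for (A in c(2, 4, 20)) {
    ab <- ecg_alphabet(A)
    x <- symbol_seq(strrep(substr(ab, 1, 1), 137), ab)
    cl <- code_length(x, fcm_empty(k = 3, alphabet = ab))
    expect_identical(cl$bits, 137 * log2(A))
  }
})

test_that("code_length equals the naive recount-per-position oracle", {
  n_cases <- 100
  mismatches <- 0
  for (case in seq_len(n_cases)) {
    A <- withr::with_seed(1000 + case, sample(2:4, 1))
    ab <- ecg_alphabet(A)
    chars <- strsplit(ab, "")[[1]]
    k <- withr::with_seed(2000 + case, sample(1:3, 1))
    nx <- withr::with_seed(3000 + case, sample(3:200, 1))
    ny <- withr::with_seed(4000 + case, sample(3:200, 1))
    x <- withr::with_seed(5000 + case, paste(sample(chars, nx, TRUE), collapse = ""))
    y <- withr::with_seed(6000 + case, paste(sample(chars, ny, TRUE), collapse = ""))
    alpha <- withr::with_seed(7000 + case, sample(alpha_grid(), 1))
    got <- relative_compression(symbol_seq(x, ab), symbol_seq(y, ab),
                                k = k, alpha = alpha)$bits
    want <- naive_code_length(x, y, k, alpha, ab)
    if (!identical(got, want)) mismatches <- mismatches + 1
  }
  expect_identical(mismatches, 0)
})

test_that("relative compression separates alien from self-similar input", {
  x <- symbol_seq("BBBB", "AB")
  y <- symbol_seq("AAAA", "AB")
  # every context of x is unseen in y's model -> uniform -> 1 bit/symbol
  for (a in c(0.01, 1)) {
    expect_equal(relative_compression(x, y, k = 1, alpha = a)$bits, 4)
  }
  rep_ab <- symbol_seq(strrep("AB", 500), "AB")
  cl <- relative_compression(rep_ab, rep_ab, k = 2, alpha = 0.01)
  expect_lt(cl$bits / 1000, 0.1)

  # probability lower bound gives a deterministic ceiling on the bits
  M <- 1000; A <- 2; a <- 0.01
  expect_lte(cl$bits, 1000 * log2((M + a * A) / a))
})

test_that("alpha resolution is deterministic and matches grid search", {
  expect_identical(resolve_alpha(0.5), 0.5)
  expect_error(resolve_alpha(-1), "positive")
  expect_error(resolve_alpha(0), "positive")

  y <- symbol_seq(strrep("AB", 500), "AB")
  got <- resolve_alpha("auto", y = y, k = 2)
  self_bits <- vapply(alpha_grid(), function(a)
    code_length(y, fcm_train(y, k = 2, alpha = a))$bits, numeric(1))
  expect_identical(got, alpha_grid()[which.min(self_bits)])
  expect_identical(resolve_alpha("auto", y = y, k = 2), got)

  # a model trained with alpha = "auto" stores the resolved value
  m <- fcm_train(y, k = 2, alpha = "auto")
  expect_identical(m$alpha, got)
  expect_identical(m$alpha_spec, "auto")
})

test_that("models round-trip losslessly through TSV serialization", {
  s <- withr::with_seed(77, paste(sample(LETTERS[1:5], 400, TRUE), collapse = ""))
  y <- symbol_seq(s, ecg_alphabet(5))
  m <- fcm_train(y, k = 3, alpha = "auto")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fcm(m, path)
  m2 <- read_fcm(path)
  expect_identical(m2$k, m$k)
  expect_identical(m2$alphabet, m$alphabet)
  expect_identical(m2$alpha, m$alpha)
  expect_identical(nrcid:::fcm_export_cpp(m2$ptr), nrcid:::fcm_export_cpp(m$ptr))
  x <- symbol_seq(withr::with_seed(78,
    paste(sample(LETTERS[1:5], 100, TRUE), collapse = "")), ecg_alphabet(5))
  expect_identical(code_length(x, m2)$bits, code_length(x, m)$bits)
})

test_that("training rejects invalid input", {
  expect_error(fcm_train(symbol_seq("AAB", "AB"), k = 0), "positive")
  expect_error(symbol_seq("AXB", "AB"), "outside alphabet")
  expect_error(code_length(symbol_seq("AA", "AB"),
                           fcm_train(symbol_seq("AAA", "ABC"), k = 1, alpha = 1)),
               "mismatch")
})
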