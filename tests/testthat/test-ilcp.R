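test_that("the interleaved LCP array of the worked example is reproduced", {
  col <- example_collection()
  idx <- build_index(col)
  ilcp <- build_ilcp(col, idx)
  expect_equal(ilcp, c(0L, 0L, 0L, 0L, 0L, 0L, 1L, 2L, 3L, 1L, 1L, 0L, 0L,
                       0L, 2L))
  enc <- encode_runs(ilcp)
  expect_equal(enc$rho, 7L)
  expect_equal(enc$VILCP, c(0L, 1L, 2L, 3L, 1L, 0L, 2L))
  expect_equal(as.integer(bv_bits(enc$L)),
               as.integer(strsplit("100000111101001", "")[[1L]]))
  expect_equal(enc$lambda, 3L)
})

test_that("interleaving satisfies its definition against per-document LCP oracles", {
  # per-document LCP computed independently by direct prefix comparison
  naive_doc_lcp <- function(text) {
    S <- c(repindex:::str_to_codes(text), 0L)
    sufs <- lapply(seq_along(S), function(i) S[i:length(S)])
    o <- order(vapply(sufs, function(s)
      paste(sprintf("%03d", s), collapse = ""), character(1L)))
    lcp <- integer(length(S))
    for (i in seq_along(o)[-1L]) {
      a <- sufs[[o[i - 1L]]]; b <- sufs[[o[i]]]
      k <- 0L
      while (k < min(length(a), length(b)) && a[k + 1L] == b[k + 1L])
        k <- k + 1L
      lcp[i] <- k
    }
    lcp
  }
  for (seed in 1:10) {
    col <- rand_collection(seed, alphabet = ALPHABETS[[1L + seed %% 3L]])
    idx <- build_index(col)
    ilcp <- build_ilcp(col, idx)
    for (j in seq_len(col$d)) {
      expect_equal(ilcp[idx$DA == j], naive_doc_lcp(col$texts[j]),
                   info = sprintf("seed %d doc %d", seed, j))
    }
  }
  # d = 1: the interleaving is the document's own LCP array
  col1 <- new_collection("BANANA")
  idx1 <- build_index(col1)
  expect_equal(build_ilcp(col1, idx1), naive_doc_lcp("BANANA"))
})

test_that("run-length encoding round-trips and degenerates correctly", {
  expect_equal(encode_runs(rep(2L, 9L))$rho, 1L)
  set.seed(31)
  for (t in 1:40) {
    x <- sample(0:4, sample(1:60, 1L), replace = TRUE)
    enc <- encode_runs(x)
    expect_identical(decode_runs(enc), x)
    expect_equal(enc$rho, bv_rank(enc$L, 1L, enc$n))
    # L' encodes every run once: total length n, rho 1-bits
    expect_equal(enc$Lprime$length, length(x))
    expect_equal(bv_rank(enc$Lprime, 1L, enc$n), enc$rho)
  }
})

test_that("listing and counting reproduce the worked example answers", {
  col <- example_collection()
  idx <- build_index(col)
  enc <- encode_runs(build_ilcp(col, idx))
  expect_equal(ilcp_list(enc, idx, 13L, 15L, 2L), c(2L, 1L))
  expect_equal(ilcp_count(enc, idx, 13L, 15L, 2L), 2L)
  # single-position interval: the one document holding that suffix
  expect_equal(ilcp_list(enc, idx, 7L, 7L, 4L), idx$DA[7L])
  expect_equal(ilcp_count(enc, idx, 7L, 7L, 1L), 1L)
})

test_that("values below the pattern length mark exactly the leftmost document occurrences", {
  bad <- character(0)
  for (seed in 1:8) {
    col <- rand_collection(seed, alphabet = ALPHABETS[[1L + seed %% 3L]])
    idx <- build_index(col)
    ilcp <- build_ilcp(col, idx)
    for (pat in all_patterns(col, 3L)) {
      iv <- search_pattern(idx, pat)
      if (is.null(iv)) next
      m <- nchar(pat)
      rng <- iv[1L]:iv[2L]
      below <- rng[ilcp[rng] < m]
      leftmost <- rng[!duplicated(idx$DA[rng])]
      if (!identical(below, leftmost)) bad <- c(bad, paste(seed, pat))
    }
  }
  expect_identical(bad, character(0))
})

test_that("listing and counting agree with the brute oracle over all short patterns", {
  bad <- character(0)
  for (seed in 1:10) {
    col <- rand_collection(seed, alphabet = ALPHABETS[[1L + seed %% 3L]])
    idx <- build_index(col)
    enc <- encode_runs(build_ilcp(col, idx))
    for (pat in all_patterns(col, 4L)) {
      iv <- search_pattern(idx, pat)
      if (is.null(iv)) next
      m <- nchar(pat)
      want <- brute_list(idx, iv[1L], iv[2L])
      if (!identical(sort(ilcp_list(enc, idx, iv[1L], iv[2L], m)), want) ||
          ilcp_count(enc, idx, iv[1L], iv[2L], m) != length(want))
        bad <- c(bad, paste(seed, pat))
    }
  }
  expect_identical(bad, character(0))
})

test_that("run counts scale with the base length plus edits, not collection size", {
  # zero-edit case: d copies of a base of length r leave at most r+1 runs
  set.seed(77)
  for (t in 1:5) {
    base <- paste(sample(c("A", "C", "G", "T"), 64L, TRUE), collapse = "")
    col <- new_collection(rep(base, 8L))
    idx <- build_index(col)
    enc <- encode_runs(build_ilcp(col, idx))
    expect_lte(enc$rho, 65L)
  }
})
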