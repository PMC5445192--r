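test_that("point mutation respects its rate and is deterministic under a seed", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 300L, TRUE), collapse = "")
  set.seed(2)
  expect_identical(mutate_seq(s, 0), s)
  set.seed(3)
  a <- mutate_seq(s, 0.3)
  set.seed(3)
  b <- mutate_seq(s, 0.3)
  expect_identical(a, b)
  expect_equal(nchar(a), nchar(s))
})

test_that("p = 1 mutation lands within binomial bounds of the expected distance", {
  # uniform 4-letter base: expected Hamming distance |S| * (1 - 1/sigma)
  len <- 400L
  sigma <- 4L
  pexp <- 1 - 1 / sigma
  for (seed in 1:20) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    m <- mutate_seq(s, 1)
    dist <- sum(strsplit(s, "")[[1L]] != strsplit(m, "")[[1L]])
    sd5 <- 5 * sqrt(len * pexp * (1 - pexp))
    expect_lte(abs(dist - len * pexp), sd5)
  }
})

test_that("mutation preserves the zero-order symbol composition", {
  set.seed(10)
  src <- paste(sample(c("A", "C", "G", "T"), 2000L, TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), collapse = "")
  p0 <- table(factor(strsplit(src, "")[[1L]], levels = c("A", "C", "G", "T")))
  p0 <- as.numeric(p0) / sum(p0)
  mut <- mutate_seq(src, 1)
  cnt <- table(factor(strsplit(mut, "")[[1L]], levels = c("A", "C", "G", "T")))
  n <- sum(cnt)
  # each symbol count within 5 sigma of its multinomial expectation
  for (i in 1:4) {
    sd5 <- 5 * sqrt(n * p0[i] * (1 - p0[i]))
    expect_lte(abs(as.numeric(cnt[i]) - n * p0[i]), sd5)
  }
})

test_that("family generators meet their counting contracts", {
  set.seed(4)
  f <- generate_collection("fig5", base_len = 128L, d = 8L, p = 0)
  expect_equal(f$d, 8L)
  expect_equal(length(unique(f$texts)), 1L)
  idx <- build_index(f)
  expect_lte(encode_runs(build_ilcp(f, idx))$rho, 129L)

  set.seed(5)
  v <- generate_collection("version", base_len = 50L, d_base = 2L,
                           variants = 3L, p = 0.05)
  expect_equal(v$d, 6L)
  set.seed(5)
  cc <- generate_collection("concat", base_len = 50L, d_base = 2L,
                            variants = 3L, p = 0.05)
  expect_equal(cc$d, 2L)
  expect_equal(sum(nchar(cc$texts)), sum(nchar(v$texts)))

  set.seed(6)
  dd <- generate_collection("dna", base_len = 40L, d_base = 3L,
                            variants = 4L, p = 0.02)
  expect_equal(dd$d, 12L)
  expect_true(all(nchar(dd$texts) == 40L))

  set.seed(7)
  g1 <- generate_collection("fig5", base_len = 64L, d = 4L, p = 0.1)
  set.seed(7)
  g2 <- generate_collection("fig5", base_len = 64L, d = 4L, p = 0.1)
  expect_identical(g1$texts, g2$texts)
})

test_that("variant pairwise distance matches the closed-form expectation", {
  # two independent mutations at rate p of the same base differ per site
  # with probability 2p(1-p)(1-1/sigma) + p^2 * (1-1/sigma) (approximately
  # 2p(1-1/sigma) for small p); test against the exact two-copy expectation
  p <- 0.05
  sigma <- 4
  q <- 1 / sigma
  # P(site differs) for entropy-preserving substitution with uniform base:
  # both mutated: (1-q); one mutated: (1-q); none: 0
  pdiff <- (2 * p * (1 - p) + p^2) * (1 - q)
  len <- 500L
  dists <- numeric(20L)
  for (seed in 1:20) {
    set.seed(seed)
    col <- generate_collection("dna", base_len = len, d_base = 1L,
                               variants = 2L, p = p)
    a <- strsplit(col$texts[1L], "")[[1L]]
    b <- strsplit(col$texts[2L], "")[[1L]]
    dists[seed] <- sum(a != b)
  }
  expected <- len * pdiff
  tol <- 5 * sqrt(len * pdiff * (1 - pdiff) / 20)
  expect_lte(abs(mean(dists) - expected), tol)
})

test_that("pattern extraction ranks by the exact statistic and is reproducible", {
  set.seed(30)
  col <- generate_collection("fig5", base_len = 60L, d = 5L, p = 0.02)
  idx <- build_index(col)
  set.seed(31)
  pats <- extract_patterns(col, length = 4L, n_sample = 500L, n_keep = 10L,
                           index = idx)
  expect_lte(nrow(pats), 10L)
  expect_true(all(diff(pats$stat) <= 1e-12))
  for (i in seq_len(nrow(pats))) {
    iv <- search_pattern(idx, pats$pattern[i])
    expect_equal(pats$occ[i], iv[2L] - iv[1L] + 1L)
    expect_equal(pats$df[i], length(brute_list(idx, iv[1L], iv[2L])))
  }
  set.seed(31)
  pats2 <- extract_patterns(col, length = 4L, n_sample = 500L, n_keep = 10L,
                            index = idx)
  expect_identical(pats, pats2)
  # n_keep beyond the distinct substring count returns everything
  set.seed(32)
  all_pats <- extract_patterns(col, length = 1L, n_sample = 2000L,
                               n_keep = 100L, index = idx)
  expect_equal(sort(all_pats$pattern),
               sort(unique(unlist(strsplit(col$texts, "")))))
  expect_warning(extract_patterns(col, length = 1000L, n_sample = 10L),
                 "long enough")
})
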