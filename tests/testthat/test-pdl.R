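test_that("set compression is lossless with terminal-only rules of length >= 2", {
  # identical sets collapse onto one rule and 1-symbol encodings
  cs <- compress_sets(rep(list(c(1L, 2L, 3L)), 4L), d = 6L)
  expect_gte(cs$n_rules, 1L)
  expect_equal(max(cs$set_end - cs$set_start) + 1L, 1L)
  for (i in 1:4) expect_equal(decompress_set(cs, i), c(1L, 2L, 3L))
  # singleton sets admit no rules (|Y| >= 2)
  cs1 <- compress_sets(list(5L, 5L, 5L), d = 6L)
  expect_equal(cs1$n_rules, 0L)
  expect_equal(decompress_set(cs1, 2L), 5L)
  # every stored rule has length >= 2
  set.seed(41)
  for (t in 1:40) {
    d <- sample(3:12, 1L)
    sets <- lapply(seq_len(sample(2:15, 1L)), function(i)
      sort(sample(d, sample(1:d, 1L))))
    cs <- compress_sets(sets, d)
    if (cs$n_rules > 0L)
      expect_true(all(cs$rule_end - cs$rule_start + 1L >= 2L))
    expect_true(all(cs$G <= d))
    for (i in seq_along(sets))
      expect_identical(decompress_set(cs, i), sets[[i]])
  }
})

test_that("sampled leaves partition the suffix array into blocks of at most b", {
  for (seed in 1:6) {
    col <- rand_collection(seed)
    idx <- build_index(col)
    st <- suffix_tree(idx)
    for (b in c(1L, 2L, 4L, 16L)) {
      pdl <- build_pdl(idx, b = b, beta = 2, st = st)
      starts <- which(bv_bits(pdl$B_L))
      expect_equal(starts, pdl$leaf_start)
      expect_equal(pdl$leaf_start[1L], 1L)
      expect_equal(pdl$leaf_end[pdl$L], col$n)
      lens <- pdl$leaf_end - pdl$leaf_start + 1L
      expect_true(all(lens >= 1L & lens <= b))
      expect_true(all(pdl$leaf_start[-1L] == pdl$leaf_end[-pdl$L] + 1L))
    }
  }
})

test_that("the pruning audit honors the storing-factor rule", {
  for (seed in 1:6) {
    col <- rand_collection(seed)
    idx <- build_index(col)
    st <- suffix_tree(idx)
    for (beta in c(1, 2, 16)) {
      pdl <- build_pdl(idx, b = 2L, beta = beta, st = st)
      aud <- pdl$audit
      expect_true(all(aud$child_total[aud$pruned] <=
                        beta * aud$dsize[aud$pruned]))
      expect_true(all(aud$child_total[!aud$pruned] >
                        beta * aud$dsize[!aud$pruned]))
    }
    # beta = Inf prunes every internal node
    pinf <- build_pdl(idx, b = 2L, beta = Inf, st = st)
    expect_equal(pinf$I, 0L)
  }
})

test_that("defaults b = 256 and beta = 16 are accepted and recorded", {
  idx <- build_index(example_collection())
  pdl <- build_pdl(idx, b = 256L, beta = 16)
  expect_equal(pdl$params$b, 256L)
  expect_equal(pdl$params$beta, 16)
  expect_error(build_pdl(idx, b = 0L), "b must be")
  expect_error(build_pdl(idx, b = 2L, beta = 0.5), "beta must be")
})

test_that("listing equals the brute oracle across the b/beta grid", {
  expect_equal({
    idx <- build_index(example_collection())
    pdl_list(build_pdl(idx, b = 1L, beta = NULL), 13L, 15L)
  }, c(1L, 2L))
  bad <- character(0)
  for (seed in 1:8) {
    col <- rand_collection(seed, alphabet = ALPHABETS[[1L + seed %% 3L]])
    idx <- build_index(col)
    st <- suffix_tree(idx)
    pdls <- list()
    for (b in c(1L, 2L, 4L, 16L))
      for (beta in list(1, 2, 16, Inf, NULL))
        pdls[[length(pdls) + 1L]] <- build_pdl(idx, b = b, beta = beta,
                                               st = st)
    for (pat in all_patterns(col, 3L)) {
      iv <- search_pattern(idx, pat)
      if (is.null(iv)) next
      want <- brute_list(idx, iv[1L], iv[2L])
      for (pdl in pdls)
        if (!identical(pdl_list(pdl, iv[1L], iv[2L]), want))
          bad <- c(bad, sprintf("seed %d pat %s b %d", seed, pat,
                                pdl$params$b))
    }
    # intervals inside a single leaf block exercise the brute fallback
    p16 <- build_pdl(idx, b = 16L, beta = 2, st = st)
    set.seed(seed)
    for (q in 1:20) {
      l <- sample(col$n, 1L)
      r <- min(col$n, l + sample(0:10, 1L))
      if (!identical(pdl_list(p16, l, r), brute_list(idx, l, r)))
        bad <- c(bad, sprintf("seed %d arbitrary [%d..%d]", seed, l, r))
    }
  }
  expect_identical(bad, character(0))
})

test_that("stored top-k lists are frequency-sorted and match brute counts", {
  bad <- character(0)
  for (seed in 1:6) {
    col <- rand_collection(seed)
    idx <- build_index(col)
    st <- suffix_tree(idx)
    pdl <- build_pdl(idx, b = 2L, beta = NULL, mode = "topk", st = st)
    for (nd in seq_len(pdl$L + pdl$I)) {
      lst <- repindex:::pdl_node_list(pdl, nd)
      ties <- split(lst$doc, lst$tf)
      want <- brute_topk(idx, pdl$node_l[nd], pdl$node_r[nd], k = col$d)
      ok <- all(diff(lst$tf) <= 0L) &&
        all(vapply(ties, function(v) all(diff(v) > 0L), logical(1L))) &&
        identical(lst$doc, want$doc) && identical(lst$tf, want$tf)
      if (!ok) bad <- c(bad, paste(seed, nd))
    }
  }
  expect_identical(bad, character(0))
})

test_that("top-k and the incremental iterator equal the brute oracle", {
  idx0 <- build_index(example_collection())
  p0 <- build_pdl(idx0, b = 1L, beta = NULL, mode = "topk")
  expect_equal(pdl_topk(p0, 13L, 15L, 1L), data.frame(doc = 1L, tf = 2L))
  bad <- character(0)
  for (seed in 1:8) {
    col <- rand_collection(seed, alphabet = ALPHABETS[[1L + seed %% 3L]])
    idx <- build_index(col)
    st <- suffix_tree(idx)
    pdls <- list(build_pdl(idx, b = 2L, beta = NULL, mode = "topk", st = st),
                 build_pdl(idx, b = 4L, beta = 2, mode = "topk", st = st))
    for (pat in all_patterns(col, 3L)) {
      iv <- search_pattern(idx, pat)
      if (is.null(iv)) next
      for (k in c(1L, 10L)) {
        want <- brute_topk(idx, iv[1L], iv[2L], k)
        for (pdl in pdls) {
          got <- pdl_topk(pdl, iv[1L], iv[2L], k)
          if (!identical(got$doc, want$doc) ||
              !identical(as.integer(got$tf), want$tf))
            bad <- c(bad, paste("topk", seed, pat, k))
        }
      }
      # the iterator yields the whole list in non-increasing tf order
      it <- pdl_topk_iter(pdls[[1L]], iv[1L], iv[2L])
      acc <- it$next_batch(2L)
      while (!it$exhausted()) acc <- rbind(acc, it$next_batch(2L))
      full <- brute_topk(idx, iv[1L], iv[2L], col$d)
      ok <- identical(acc$doc, full$doc) &&
        identical(as.integer(acc$tf), full$tf) && it$peek_tf() == 0L
      if (!ok) bad <- c(bad, paste("iter", seed, pat))
    }
  }
  expect_identical(bad, character(0))
})

test_that("k >= d returns every matching document, frequency-sorted", {
  col <- example_collection()
  idx <- build_index(col)
  pdl <- build_pdl(idx, b = 2L, beta = NULL, mode = "topk")
  iv <- search_pattern(idx, "A")
  got <- pdl_topk(pdl, iv[1L], iv[2L], 10L)
  expect_equal(got, brute_topk(idx, iv[1L], iv[2L], 10L))
  expect_error(pdl_topk(pdl, iv[1L], iv[2L], 0L), "k must be")
})
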