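# The central property: BitBound-pruned searches return exactly what an
# unpruned linear scan returns, across thresholds, k values and bit sizes.

test_that("threshold search equals the brute-force linear scan", {
  set.seed(41)
  for (setup in list(list(nb = 21L, bits = 166L, dens = 0.25),
                     list(nb = 111L, bits = 881L, dens = 0.10))) {
    recs <- random_records(1500, setup$nb, setup$bits, density = setup$dens)
    ar <- fp_arena(recs)
    aligned <- as_fps_records(ar)  # oracle indexed in arena order
    for (T in c(0.4, 0.7, 0.9)) {
      rt <- rational_threshold(T)
      for (rep in 1:8) {
        q <- random_fp(setup$nb, setup$bits, setup$dens)
        hits <- search_threshold(ar, q, rt)
        oracle <- brute_threshold(aligned, q, rt)
        expect_identical(hits$index, oracle$hits)
        expect_identical(hits$score, oracle$scores[oracle$hits])
        # completeness: every non-hit really scores below T
        expect_true(all(oracle$scores[-oracle$hits] < T + 1e-9) ||
                      length(oracle$hits) == 0)
      }
    }
  }
})

test_that("threshold search handles the documented edge cases", {
  set.seed(42)
  fps <- c(list(hex_to_fp("c218"), hex_to_fp("c218"), raw(2)),
           lapply(1:5, function(i) random_fp(2L)))
  recs <- fps_records(paste0("m", 1:8), fps, metadata = fp_metadata(16))
  ar <- fp_arena(recs)
  # T=1 with a duplicated query: exactly the identical targets
  h <- search_threshold(ar, hex_to_fp("c218"), 1)
  expect_equal(sort(ar$ids[h$index]), c("m1", "m2"))
  expect_equal(h$score, c(1, 1))
  # all-zero query, T>0: nothing (zero-popcount convention)
  expect_equal(nrow(search_threshold(ar, raw(2), 0.1)), 0L)
  # T=0 returns everything; the zero/zero pair scores 0
  h0 <- search_threshold(ar, raw(2), 0)
  expect_equal(nrow(h0), 8L)
  expect_true(all(h0$score == 0))
  # length mismatch is an error
  expect_error(search_threshold(ar, raw(3), 0.5), "bytes")
})

test_that("threshold hits are monotone in the threshold", {
  set.seed(43)
  recs <- random_records(800, 21L, 166L, density = 0.25)
  ar <- fp_arena(recs)
  for (rep in 1:5) {
    q <- random_fp(21L, 166L, 0.25)
    prev <- NULL
    for (T in c(0.2, 0.4, 0.6, 0.8, 0.95)) {
      ids <- search_threshold(ar, q, T)$index
      if (!is.null(prev)) expect_true(all(ids %in% prev))
      prev <- ids
    }
  }
})

test_that("k-nearest equals brute-force top-k, heap and counting agree", {
  set.seed(44)
  recs <- random_records(1200, 21L, 166L, density = 0.25)
  ar <- fp_arena(recs)
  aligned <- as_fps_records(ar)
  for (rep in 1:12) {
    q <- random_fp(21L, 166L, 0.25)
    for (k in c(1L, 10L, 100L)) {
      heap <- search_knearest(ar, q, k, method = "heap")
      cnt <- search_knearest(ar, q, k, method = "counting")
      oracle <- brute_knearest(aligned, q, k)
      expect_identical(heap$index, oracle$index)
      expect_identical(heap$score, oracle$score)
      expect_identical(cnt$index, heap$index)
      expect_identical(cnt$score, heap$score)
      # scores sorted descending; ties broken by ascending index
      expect_true(all(diff(heap$score) <= 0))
    }
    # prefix property under the documented tie-break
    k10 <- search_knearest(ar, q, 10L)
    k11 <- search_knearest(ar, q, 11L)
    expect_identical(k11$index[1:10], k10$index)
  }
})

test_that("k-nearest edge cases and the minimum threshold filter", {
  set.seed(45)
  recs <- random_records(300, 8L, density = 0.3)
  ar <- fp_arena(recs)
  aligned <- as_fps_records(ar)
  q <- fps_fingerprint(recs, 5)
  # query identical to a target: that target first at 1.0
  k1 <- search_knearest(ar, q, 1L)
  expect_equal(k1$score, 1)
  expect_equal(fp_to_hex(arena_fingerprint(ar, k1$index)), fp_to_hex(q))
  # exact duplicates resolve to the lowest arena index
  dup_idx <- which(vapply(seq_len(ar$n), function(i)
    identical(arena_fingerprint(ar, i), q), TRUE))
  expect_equal(k1$index, min(dup_idx))
  # k >= n gives the full descending ranking
  kall <- search_knearest(ar, q, 1000L)
  expect_equal(nrow(kall), ar$n)
  expect_true(all(diff(kall$score) <= 0))
  # min_threshold is a hard filter: may return fewer than k
  rt <- rational_threshold(0.8)
  kf <- search_knearest(ar, q, 50L, threshold = rt)
  oracle <- brute_knearest(aligned, q, 50L, rt)
  expect_identical(kf$index, oracle$index)
  expect_true(all(kf$score >= 0.8 - 1e-12))
  expect_error(search_knearest(ar, q, 0L), "positive")
})

test_that("an all-zero query ranks everything at score 0", {
  recs <- fps_records(c("a", "b", "c"),
                      lapply(c("00", "01", "ff"), hex_to_fp))
  ar <- fp_arena(recs)
  k <- search_knearest(ar, raw(1), 2L)
  expect_equal(k$score, c(0, 0))
  expect_equal(k$index, c(1L, 2L))     # ascending-index ties
  expect_equal(nrow(search_knearest(ar, raw(1), 2L, threshold = 0.5)), 0L)
})

test_that("counting-sort buckets are bounded by the distinct score count", {
  set.seed(46)
  recs <- random_records(400, 8L, density = 0.4)
  ar <- fp_arena(recs)
  q <- random_fp(8L, density = 0.4)
  kall <- search_knearest(ar, q, 400L, method = "counting")
  # number of distinct scores is at most the number of (c, d) pairs
  A <- oracle_popcount(q)
  pairs <- expand.grid(cc = 0:A, B = 0:64)
  expect_lte(length(unique(kall$score)), nrow(unique(pairs)))
  # all targets identical: one bucket, first k indices
  same <- fps_records(paste0("s", 1:20),
                      rep(list(hex_to_fp("c218")), 20))
  ars <- fp_arena(same)
  ks <- search_knearest(ars, hex_to_fp("c218"), 5L, method = "counting")
  expect_equal(ks$index, 1:5)
  expect_equal(ks$score, rep(1, 5))
})

test_that("multiquery results are invariant to workers and query order", {
  set.seed(47)
  recs <- random_records(600, 21L, 166L, density = 0.25)
  ar <- fp_arena(recs)
  queries <- random_records(40, 21L, 166L, density = 0.25, prefix = "Q")
  base <- search_multiquery(ar, queries, "threshold", threshold = 0.5)
  expect_length(base, 40L)
  expect_equal(attr(base[[3]], "query_id"), "Q3")
  par4 <- search_multiquery(ar, queries, "threshold", threshold = 0.5,
                            workers = 4L)
  srt <- search_multiquery(ar, queries, "threshold", threshold = 0.5,
                           sort_queries = TRUE)
  for (j in seq_along(base)) {
    expect_identical(par4[[j]]$index, base[[j]]$index)
    expect_identical(srt[[j]]$index, base[[j]]$index)
    expect_identical(base[[j]]$index,
                     search_threshold(ar, fps_fingerprint(queries, j),
                                      0.5)$index)
  }
  expect_equal(search_multiquery(ar, list(), "threshold", threshold = 0.5),
               list())
  expect_error(search_multiquery(ar, queries, workers = 0L), "positive")
})

test_that("symmetric search equals N x M of the arena against itself", {
  set.seed(48)
  pool <- random_records(60, 21L, 166L, density = 0.25)
  idx <- sample(60, 400, replace = TRUE)
  recs <- fps_records(paste0("r", seq_along(idx)), pool$block[
    rep((idx - 1L) * 21L, each = 21L) + 1:21], metadata = pool$metadata)
  ar <- fp_arena(recs)
  sym <- search_symmetric(ar, "threshold", threshold = 0.8)
  # oracle: multiquery of the arena against itself, self-pairs removed
  mq <- search_multiquery(ar, as_fps_records(ar), "threshold",
                          threshold = 0.8)
  oracle <- do.call(rbind, lapply(seq_along(mq), function(i) {
    h <- mq[[i]]
    if (nrow(h)) data.frame(i = i, j = h$index, score = h$score)
  }))
  oracle <- oracle[oracle$i != oracle$j, ]
  oracle <- oracle[order(oracle$i, oracle$j), ]
  expect_equal(sym$i, oracle$i)
  expect_equal(sym$j, oracle$j)
  expect_equal(sym$score, oracle$score)
  # symmetry: entry count even, every (i,j) mirrored
  expect_equal(nrow(sym) %% 2, 0)
  expect_true(all(paste(sym$i, sym$j) %in% paste(sym$j, sym$i)))
  expect_true(all(sym$i != sym$j))  # diagonal absent

  # k-nearest mode: per-row top-k excluding self
  ks <- search_symmetric(ar, "knearest", k = 3L)
  for (i in c(1L, 50L, 400L)) {
    expect_false(i %in% ks[[i]]$index)
    q <- arena_fingerprint(ar, i)
    oracle_k <- brute_knearest(as_fps_records(ar), q, 4L)
    expect_identical(ks[[i]]$index,
                     head(setdiff(oracle_k$index, i), 3L))
  }
  expect_error(search_symmetric(fp_arena(recs, sort = FALSE)), "sorted")
})

test_that("three identical fingerprints give all six off-diagonal pairs", {
  recs <- fps_records(c("a", "b", "c"), rep(list(hex_to_fp("c218")), 3))
  sym <- search_symmetric(fp_arena(recs), "threshold", threshold = 0.9)
  expect_equal(nrow(sym), 6L)
  expect_true(all(sym$score == 1))
})

test_that("file-scan search matches the arena search", {
  set.seed(49)
  recs <- random_records(800, 21L, 166L, density = 0.25)
  path <- tempfile(fileext = ".fps")
  write_fps(recs, path)
  ar <- fp_arena(recs)
  for (rep in 1:5) {
    q <- random_fp(21L, 166L, 0.25)
    scan <- search_fps_file(path, q, "threshold", threshold = 0.5)
    mem <- search_threshold(ar, q, 0.5)
    expect_equal(sort(paste(scan$id, scan$score)),
                 sort(paste(mem$id, mem$score)))
    # threshold-mode hits come in file order
    expect_true(all(diff(scan$recno) > 0))
    kscan <- search_fps_file(path, q, "knearest", k = 10L)
    kmem <- search_knearest(ar, q, 10L)
    expect_equal(kscan$score, kmem$score)
    # hits strictly above the k-th score are identical; members tied at
    # the k-th score may differ (file order vs arena order) but must
    # genuinely score the k-th value
    kth <- min(kmem$score)
    expect_equal(sort(kscan$id[kscan$score > kth]),
                 sort(kmem$id[kmem$score > kth]))
    for (id in kscan$id[kscan$score == kth]) {
      i <- match(id, recs$ids)
      expect_equal(tanimoto(q, fps_fingerprint(recs, i)), kth)
    }
  }
})

test_that("k-nearest file scan stops early after k exact matches", {
  lines <- c("#FPS1", "#num_bits=16",
             "c218\tfirst", "0100\tother", "not a valid line")
  path <- write_lines_tmp(lines)
  # the exact match on record 1 permits early exit: the corrupt line 5 is
  # never validated
  res <- search_fps_file(path, hex_to_fp("c218"), "knearest", k = 1L)
  expect_equal(res$id, "first")
  expect_equal(res$score, 1)
  expect_equal(attr(res, "stats")$scanned, 1L)
  # threshold mode validates the whole file even below the threshold
  expect_error(search_fps_file(path, hex_to_fp("c218"), "threshold",
                               threshold = 0.9), "line 5")
})

test_that("tversky searches filter and rank with integer arithmetic", {
  set.seed(50)
  recs <- random_records(600, 21L, 166L, density = 0.25)
  ar <- fp_arena(recs)
  aligned <- as_fps_records(ar)
  q <- fps_fingerprint(recs, 10)
  # alpha = beta = 1 reduces to tanimoto
  t1 <- search_threshold(ar, q, 0.5, similarity = "tversky",
                         alpha = 1, beta = 1)
  t2 <- search_threshold(ar, q, 0.5)
  expect_identical(t1$index, t2$index)
  expect_equal(t1$score, t2$score)
  # asymmetric weights match the per-pair tversky() on every target
  h <- search_threshold(ar, q, 0.35, similarity = "tversky",
                        alpha = 0.3, beta = 0.7)
  all_scores <- vapply(seq_len(ar$n), function(i)
    tversky(q, fps_fingerprint(aligned, i), 0.3, 0.7), numeric(1))
  expect_identical(h$index, which(all_scores >= 0.35))
  expect_equal(h$score, all_scores[h$index])
  # k-nearest tversky: self first at exactly 1
  kk <- search_knearest(ar, q, 5L, similarity = "tversky",
                        alpha = 2, beta = 0.5)
  expect_identical(kk$score[1], 1)
})

test_that("duplicate fingerprints are never merged", {
  recs <- fps_records(paste0("d", 1:4),
                      rep(list(hex_to_fp("0f00")), 4))
  ar <- fp_arena(recs)
  h <- search_threshold(ar, hex_to_fp("0f00"), 0.9)
  expect_equal(nrow(h), 4L)
  k <- search_knearest(ar, hex_to_fp("0f00"), 10L)
  expect_equal(nrow(k), 4L)
})
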