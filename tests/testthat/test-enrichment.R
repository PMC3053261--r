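test_that("one-tailed Fisher matches hand-enumerated tails and edge cases", {
  # draw 5 of 10, 4 marked, observe 3: tail = 66/252
  expect_equal(fisher_one_tailed(3, 2, 1, 4), 66 / 252, tolerance = 1e-12)
  # every gene in the set -> saturated margin, p = 1
  expect_equal(fisher_one_tailed(5, 0, 7, 0), 1)
  # empty overlap -> P(X >= 0) = 1
  expect_equal(fisher_one_tailed(0, 5, 4, 6), 1)
  expect_error(fisher_one_tailed(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher agrees with the exhaustive hypergeometric oracle on small tables", {
  # sweep a grid of tables with N <= 60 against the pmf-summing oracle
  set.seed(14)
  for (N in c(8L, 21L, 40L, 60L)) {
    for (rep in 1:80) {
      a <- sample.int(N, 1) - 1L
      b <- sample.int(N - a, 1) - 1L
      c <- sample.int(max(N - a - b, 1), 1) - 1L
      d <- N - a - b - c
      if (d < 0) next
      p_mine <- fisher_one_tailed(a, b, c, d)
      p_orc <- fisher_oracle(a, b, c, d)
      expect_equal(p_mine, p_orc, tolerance = 1e-12)
      # and against the standard exact test
      p_ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                 alternative = "greater")$p.value
      expect_equal(p_mine, p_ft, tolerance = 1e-9)
    }
  }
})

test_that("Fisher p is transpose-symmetric, monotone in a, and underflow-safe", {
  expect_equal(fisher_one_tailed(4, 3, 2, 8), fisher_one_tailed(4, 2, 3, 8),
               tolerance = 1e-12)
  # with margins fixed, larger observed overlap is never less surprising
  n <- 12L; K <- 10L; N <- 30L
  ps <- vapply(0:min(n, K), function(a)
    fisher_one_tailed(a, n - a, K - a, N - n - K + a), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  # log-space stability: the large response-overlap table stays positive
  p_big <- fisher_one_tailed(1567, 635, 3606, 8412)
  expect_gt(p_big, 0)
  expect_lt(p_big, 1e-100)
  lp <- fisher_one_tailed(1567, 635, 3606, 8412, log.p = TRUE)
  expect_equal(exp(lp), p_big)
})

test_that("fold enrichment reproduces the published arithmetic", {
  expect_equal(fold_enrichment(9, 101, 154, 14220)$fold, 8.23, tolerance = 0.01)
  expect_equal(fold_enrichment(1567, 2202, 5173, 14220)$fold, 1.96, tolerance = 0.01)
  flat <- fold_enrichment(5, 50, 100, 1000)
  expect_equal(flat$fold, 1)
  expect_equal(flat$expected, 5)
  expect_error(fold_enrichment(1, 0, 5, 10), "positive")
})

test_that("set enrichment applies the Bonferroni threshold over the scan", {
  set.seed(77)
  universe <- paste0("g", 1:200)
  sets <- stats::setNames(lapply(1:26, function(i) sample(universe, 30)),
                          sprintf("bp%02d", 1:26))
  coll <- gene_set_collection(sets, top_level = names(sets))
  target <- universe[1:40]
  res <- enrich_sets(target, coll, universe, alpha = 0.05)
  expect_equal(unique(res$threshold), 0.05 / 26)
  expect_equal(signif(unique(res$threshold), 1), 0.002)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # disjoint target and set -> a = 0 and p = 1
  coll2 <- gene_set_collection(list(s = universe[100:120]))
  res2 <- enrich_sets(universe[1:10], coll2, universe, correction = "none")
  expect_equal(res2$a, 0L)
  expect_equal(res2$p, 1)
  expect_error(enrich_sets(c(target, "novel"), coll, universe), "novel")
})

test_that("overlap analysis reports both conditional shares", {
  universe <- paste0("g", 1:2000)
  bound <- universe[1:200]
  de <- universe[c(1:120, 500:1000)]
  ov <- overlap_analysis(bound, de, universe)
  expect_equal(ov$overlap, 120L)
  expect_equal(ov$share1, 120 / 200)
  expect_equal(ov$share2, 120 / length(de))
  # identical sets: maximal overlap, minimal p for the margins
  same <- overlap_analysis(bound, bound, universe)
  expect_equal(same$share1, 1)
  expect_lt(same$result$p, fisher_one_tailed(199, 1, 1, 1799))
  expect_error(overlap_analysis(character(0), de, universe), "non-empty")
  # the array-margin construction re-counts set1 in the comparison column
  arr <- overlap_analysis(bound, de, universe, margin = "array")
  expect_equal(arr$result$c, length(de))
  expect_gt(arr$result$p, ov$result$p)
})

test_that("random same-size sets show no spurious overlap signal", {
  set.seed(31)
  universe <- paste0("g", 1:1500)
  hits <- vapply(1:50, function(i) {
    s1 <- sample(universe, 150)
    s2 <- sample(universe, 400)
    overlap_analysis(s1, s2, universe)$result$p
  }, numeric(1))
  expect_gte(mean(hits > 0.05), 0.9)
})
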