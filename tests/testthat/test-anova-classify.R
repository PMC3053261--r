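test_that("two-way ANOVA matches the frozen worked example", {
  # cells (log2): ctrl{0,1}, cyt{0,1}, sh{2,3}, both{2,3}
  x <- toy_log2_matrix(c(0, 1, 0, 1, 2, 3, 2, 3))
  rec <- anova_two_way(x, toy_design())
  expect_equal(rec$F1, 16)
  expect_equal(rec$F2, 0)
  expect_equal(rec$F12, 0)
  expect_equal(rec$df_resid, 4L)
})

test_that("ANOVA agrees with a least-squares oracle on random balanced layouts", {
  set.seed(101)
  design <- toy_design(r = 4L)
  for (case in 1:200) {
    y <- rnorm(16, mean = sample(4:10, 1), sd = runif(1, 0.1, 2))
    mine <- anova_two_way(toy_log2_matrix(y, r = 4L), design)
    orc <- anova_oracle(y, design)
    expect_equal(mine$F1, orc$F1, tolerance = 1e-10)
    expect_equal(mine$F2, orc$F2, tolerance = 1e-10)
    expect_equal(mine$F12, orc$F12, tolerance = 1e-10)
    expect_equal(mine$p1, orc$p1, tolerance = 1e-10)
    expect_equal(mine$p12, orc$p12, tolerance = 1e-10)
  }
})

test_that("sum-of-squares decomposition is conserved", {
  set.seed(55)
  design <- toy_design(r = 4L)
  x <- matrix(rnorm(50 * 16, 8, 1.5), 50, 16,
              dimnames = list(paste0("p", 1:50), design$sample_id))
  rec <- anova_two_way(x, design)
  ss_tot <- rowSums((x - rowMeans(x))^2)
  n <- 16
  ss_eff <- n * rec$contrast1^2 / 4 + n * rec$contrast2^2 / 4 +
    n * rec$contrast12^2 / 16 + rec$ms_resid * rec$df_resid
  expect_lt(max(abs(ss_eff - ss_tot) / ss_tot), 1e-9)
})

test_that("degenerate and invariance conventions hold", {
  # all 16 values equal -> F = 0, p = 1 everywhere
  rec <- anova_two_way(toy_log2_matrix(rep(2, 16), r = 4L), toy_design(r = 4L))
  expect_equal(c(rec$F1, rec$F2, rec$F12), c(0, 0, 0))
  expect_equal(c(rec$p1, rec$p2, rec$p12), c(1, 1, 1))

  # affine transforms leave F and p unchanged
  y <- c(0.3, 1.2, 0.8, 1.9, 3.1, 2.2, 2.7, 3.3)
  r1 <- anova_two_way(toy_log2_matrix(y), toy_design())
  r2 <- anova_two_way(toy_log2_matrix(-2.5 * y + 7), toy_design())
  expect_equal(r1$F1, r2$F1)
  expect_equal(r1$p12, r2$p12)

  # unbalanced or under-replicated designs are rejected
  d <- toy_design(r = 2L)
  expect_error(anova_two_way(toy_log2_matrix(y)[, -1, drop = FALSE], d[-1, ]),
               "unbalanced")
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  set.seed(2)
  p <- runif(100)
  q <- fdr_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("category assignment follows the interaction-dominant rule", {
  rec <- data.frame(probeset_id = paste0("p", 1:5),
                    m_ctrl = 5, m_cyt = c(5, 6, 6, 5, 5),
                    m_sh = c(7, 5, 7, 5, 7), m_both = c(7, 6, 8, 6, 5),
                    contrast1 = c(2, 0, 1.5, 0.5, 1),
                    contrast2 = c(0, 1, 1, 1, -1),
                    contrast12 = c(0, 0, 0, 1, -4),
                    q1 = c(0.001, 0.5, 0.004, 0.5, 0.002),
                    q2 = c(0.5, 0.003, 0.006, 0.5, 0.5),
                    q12 = c(0.5, 0.5, 0.5, 0.004, 0.009))
  calls <- classify_probesets(rec, classify_config(alpha_fdr = 0.01))
  expect_equal(calls$category, c("A", "B", "C", "D", "D"))
  expect_equal(calls$dir_factor1, c("up", "n/a", "up", "n/a", "up"))
  expect_equal(calls$dir_factor2, c("n/a", "up", "up", "n/a", "n/a"))
  # fold changes: A uses the factor-1 marginal, C the larger marginal,
  # D the largest treated-vs-control cell contrast
  expect_equal(calls$fold_change, 2^c(2, 1, 1.5, 1, 2))
  expect_equal(calls$passes_2fold, c(TRUE, TRUE, TRUE, TRUE, TRUE))
  strict <- classify_probesets(rec, classify_config(fold_threshold = 3))
  expect_equal(strict$passes_2fold, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("every probeset receives exactly one category", {
  bun <- simulate_expression(sim_config(n_genes = 300L, seed = 8L))$bundle
  calls <- classify_probesets(add_fdr(anova_two_way(bun)))
  expect_equal(nrow(calls), nrow(bun$values))
  expect_true(all(calls$category %in% c("A", "B", "C", "D", "none")))
  expect_false(any(duplicated(calls$probeset_id)))
})

test_that("summary counts and overlap shares reproduce the published arithmetic", {
  # printed counts: share of cytokine-responsive probesets also knock-down
  # responsive, at both cut-offs
  expect_equal(report_overlap_shares(c(A = 3606, B = 635, C = 1065, D = 502))$
                 share_factor2_also_factor1, 1567 / 2202)
  expect_equal(round(100 * report_overlap_shares(
    c(A = 878, B = 78, C = 223, D = 296))$share_factor2_also_factor1), 87)

  empty <- summarize_categories(
    data.frame(probeset_id = character(0), category = character(0),
               dir_factor1 = character(0), dir_factor2 = character(0),
               fold_change = numeric(0), passes_2fold = logical(0)))
  expect_true(all(empty$n_fdr == 0))
  shares <- report_overlap_shares(empty)
  expect_true(all(is.na(shares$share_factor2_also_factor1)))
})
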