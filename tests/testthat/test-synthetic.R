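test_that("generator is deterministic and honours the null model", {
  cfg <- sim_config(n_genes = 200L, seed = 42L)
  a <- simulate_bundle(cfg)
  b <- simulate_bundle(cfg)
  expect_identical(a$bundle$values, b$bundle$values)
  expect_identical(a$truth, b$truth)
  expect_identical(unclass(a$promoters), unclass(b$promoters))
  expect_identical(a$bound, b$bound)

  # all effect ranges zero -> every gene truly null
  null_cfg <- sim_config(n_genes = 100L, effect_range = c(0, 0),
                         category_props = c(A = 0, B = 0, C = 0, D = 0),
                         seed = 3L)
  tr <- simulate_expression(null_cfg)$truth
  expect_true(all(tr$category == "none"))
  expect_true(all(tr$beta_sh == 0 & tr$beta_cyt == 0 & tr$beta_int == 0))
})

test_that("truth-table effects are consistent with categories", {
  tr <- simulate_expression(sim_config(n_genes = 1000L, seed = 5L))$truth
  expect_true(all(tr$beta_cyt[tr$category == "A"] == 0))
  expect_true(all(tr$beta_int[tr$category == "A"] == 0))
  expect_true(all(tr$beta_sh[tr$category == "B"] == 0))
  expect_true(all(tr$beta_int[tr$category == "C"] == 0))
  expect_true(all(tr$beta_sh[tr$category == "C"] != 0))
  expect_true(all(tr$beta_int[tr$category == "D"] != 0))
  expect_true(all(is.na(tr$archetype) == (tr$category != "D")))
  expect_true(all(tr$archetype[tr$category == "D"] %in% c(
    "down_sh_only", "up_both_only", "up_sh_only", "down_both_only",
    "up_cyt_only", "down_cyt_only", "singles_up_combo_null",
    "singles_down_combo_null")))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(category_props = c(A = 0.5, B = 0.3, C = 0.2, D = 0.2)),
               "at most 1")
  expect_error(sim_config(sigma = 0), "sigma")
  expect_error(sim_config(replicates = 1L), "replicates")
  expect_error(sim_config(category_props = c(A = 0.5, B = 0.2, C = 0.2, D = 0.1),
                          fdr_calibration = TRUE),
               "null-category")
})

test_that("promoter generator plants the motif as configured", {
  cfg <- sim_config(n_genes = 60L, p_responsive = 1, p_background = 0,
                    promoter_length = 300L, seed = 9L)
  expr <- simulate_expression(cfg)
  prom <- simulate_promoters(cfg, expr$truth)
  responsive <- expr$truth$category != "none"
  expect_true(all(prom$planted[responsive]))
  expect_false(any(prom$planted[!responsive]))

  model <- build_motif_model(prom$pfms$ETSLIKE, name = "ETSLIKE")
  hits <- motif_presence(prom$promoters, model)
  expect_true(all(hits[expr$truth$gene_id[responsive]]))

  short <- sim_config(n_genes = 10L, promoter_length = 5L)
  expect_error(simulate_promoters(short, expr$truth[1:10, ]), "longer than promoter")
})

test_that("bound-list generator enriches responsive genes and validates size", {
  cfg <- sim_config(n_genes = 500L, bound_odds_ratio = 3, seed = 21L)
  expr <- simulate_expression(cfg)
  over_bg <- vapply(1:20, function(s) {
    cfg_s <- sim_config(n_genes = 500L, bound_odds_ratio = 3, seed = 21L + s)
    bound <- simulate_bound_list(cfg_s, expr$truth, size = 100L)
    resp <- expr$truth$gene_id[expr$truth$category %in% c("A", "C", "D")]
    mean(bound %in% resp) > mean(expr$truth$gene_id %in% resp)
  }, logical(1L))
  expect_gte(mean(over_bg), 0.95)

  expect_error(simulate_bound_list(cfg, expr$truth, size = 501L), "exceeds")
  expect_identical(simulate_bound_list(cfg, expr$truth, size = 0L), character(0L))
})

test_that("raising the noise level never improves mean category recovery", {
  accuracy <- function(sigma, s) {
    cfg <- sim_config(n_genes = 400L, effect_range = c(2, 3), sigma = sigma,
                      multi_probeset_rate = 0, seed = 600L + s)
    sim <- simulate_expression(cfg)
    calls <- classify_probesets(add_fdr(anova_two_way(sim$bundle)))
    truth_cat <- stats::setNames(sim$truth$category, sim$truth$gene_id)
    nn <- calls$category != "none" | truth_cat[unname(sim$gene_map[calls$probeset_id])] != "none"
    mean((calls$category == truth_cat[unname(sim$gene_map[calls$probeset_id])])[nn])
  }
  acc <- vapply(c(0.25, 1.5, 3), function(sg)
    mean(vapply(1:10, function(s) accuracy(sg, s), numeric(1))), numeric(1))
  expect_true(all(diff(acc) < 0))
})

test_that("written bundle directory round-trips through the readers", {
  cfg <- sim_config(n_genes = 40L, promoter_length = 120L, seed = 13L)
  bun <- simulate_bundle(cfg)
  dir <- withr::local_tempdir()
  write_bundle(bun, dir)

  back <- read_expression(file.path(dir, "matrix.tsv"), file.path(dir, "samples.tsv"))
  expect_equal(dim(back$values), dim(bun$bundle$values))
  expect_lt(max(abs(back$values - bun$bundle$values) / bun$bundle$values), 1e-6)
  expect_identical(read_gene_map(file.path(dir, "gene_map.tsv")), bun$gene_map)
  prom_back <- read_fasta_promoters(file.path(dir, "promoters.fasta"))
  expect_identical(setNames(as.character(prom_back), names(prom_back)),
                   setNames(as.character(bun$promoters), names(bun$promoters)))
  expect_equal(read_jaspar_pfm(file.path(dir, "motifs.pfm"))$ETSLIKE,
               bun$pfms$ETSLIKE, tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(read_gene_list(file.path(dir, "bound.txt")), bun$bound)
  gmt <- read_gmt(file.path(dir, "sets.gmt"))
  expect_setequal(gmt$inflammatory_response,
                  bun$truth$gene_id[bun$truth$inflammatory])
})
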