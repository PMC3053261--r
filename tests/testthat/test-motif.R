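test_that("promoter extraction honours window, strand and clipping rules", {
  genome <- paste(rep("ACGT", 800), collapse = "")  # 3200 bp contig
  p <- extract_promoter(genome, tss = 1500, strand = "+", up = 1000, down = 500)
  expect_equal(nchar(p), 1500L)
  expect_equal(p, substr(genome, 501, 2000))
  # minus strand mirrors the window and reverse-complements
  m <- extract_promoter(genome, tss = 1500, strand = "-", up = 1000, down = 500)
  expect_equal(m, reverse_complement(substr(genome, 1001, 2500)))
  # extended scan window
  genome2 <- strrep("A", 9000)
  expect_equal(nchar(extract_promoter(genome2, 5500, "+", up = 5000, down = 2500)),
               7500L)
  expect_warning(extract_promoter(genome, tss = 100, strand = "+"), "clipped")
  expect_error(extract_promoter(genome, tss = 5000, strand = "+"), "outside")
})

test_that("motif model probabilities and consensus follow the pseudocount rule", {
  pfm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm[cbind(c(1, 2, 3, 4), 1:4)] <- 8
  model <- build_motif_model(pfm, background = rep(0.25, 4), pseudocount = 4)
  # column (8,0,0,0) with one pseudocount per base: p = 9/12, log2(3)
  expect_equal(unname(model$pwm["A", 1]), log2(3), tolerance = 1e-12)
  expect_equal(unname(model$pwm["C", 1]), log2((1 / 12) / 0.25), tolerance = 1e-12)
  expect_equal(model$consensus, "ACGT")
  # balanced column against its own background scores zero
  flat <- build_motif_model(matrix(2, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_true(all(abs(flat$pwm) < 1e-12))
  # pseudocounted probabilities stay normalized
  prob <- 2^model$pwm * 0.25
  expect_equal(unname(colSums(prob)), rep(1, 4), tolerance = 1e-12)
  expect_error(build_motif_model(pfm, background = c(0, 0.5, 0.25, 0.25)),
               "positive")
  # the ETS-like planted matrix recovers its published-style consensus
  ets <- build_motif_model(planted_ets_pfm())
  expect_match(ets$consensus, "CCGGAA")
})

test_that("scanner agrees exactly with a naive per-window rescorer", {
  set.seed(23)
  for (case in 1:40) {
    L <- sample(5:9, 1)
    pfm <- matrix(runif(4 * L, 0, 20), 4, L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    model <- build_motif_model(pfm, threshold = -1e9)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    hits <- scan_motif(model, seq)
    fwd <- naive_window_scores(model, seq)
    got_fwd <- hits$score[hits$strand == "+"][order(hits$offset[hits$strand == "+"])]
    expect_equal(got_fwd, fwd[is.finite(fwd)], tolerance = 1e-12)
  }
})

test_that("hits are strand-symmetric and threshold-monotone", {
  model <- build_motif_model(planted_ets_pfm(), threshold = 8)
  seq <- paste0(strrep("T", 30), "CCGGAAG", strrep("C", 25))
  hits <- scan_motif(model, seq)
  expect_true(any(hits$strand == "+" & hits$offset == 30 & hits$score >= 8))
  rc_hits <- scan_motif(model, reverse_complement(seq))
  expect_equal(sort(rc_hits$score), sort(hits$score), tolerance = 1e-12)
  expect_setequal(rc_hits$offset, nchar(seq) - model$length - hits$offset)

  # shorter than the motif: no hits, no error
  expect_equal(nrow(scan_motif(model, "CCG")), 0L)

  # presence is monotone in the threshold
  prom <- promoter_set(c(g1 = seq, g2 = strrep("A", 40), g3 = strrep("N", 40)))
  loose <- build_motif_model(planted_ets_pfm(), threshold = 2)
  tight <- build_motif_model(planted_ets_pfm(), threshold = 12)
  p_loose <- motif_presence(prom, loose)
  p_tight <- motif_presence(prom, tight)
  expect_true(all(p_loose >= p_tight))
  expect_true(p_loose[["g1"]])
  expect_false(p_loose[["g3"]])
})

test_that("presence-based enrichment builds the expected table and threshold", {
  set.seed(87)
  model_pfm <- planted_ets_pfm()
  plant <- function(n, rate, len = 120L) {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    hit <- seq_len(n) <= round(rate * n)
    seqs[hit] <- vapply(seqs[hit], function(s) {
      substr(s, 50, 56) <- "CCGGAAG"; s
    }, character(1))
    stats::setNames(seqs, sprintf("t%03d_%d", seq_len(n), rate * 100))
  }
  target <- promoter_set(plant(40, 0.8))
  bg <- promoter_set(stats::setNames(unname(plant(60, 0.1)), sprintf("b%03d", 1:60)))
  res <- motif_enrich(target, bg, list(ETSLIKE = model_pfm), alpha = 0.05)
  expect_equal(res$a + res$b, 40)
  expect_equal(res$c + res$d, 60)
  expect_lt(res$p, 0.05)

  # Bonferroni over the motif family: ~140 matrices gives the 3.5e-4 cut-off
  many <- c(list(ETSLIKE = model_pfm),
            stats::setNames(replicate(139, model_pfm, simplify = FALSE),
                            sprintf("m%03d", 1:139)))
  res140 <- motif_enrich(target, bg, many, alpha = 0.05)
  expect_equal(unique(res140$threshold), 0.05 / 140)
  expect_equal(signif(unique(res140$threshold), 2), 3.6e-4)
  expect_error(motif_enrich(promoter_set(character(0)), bg, list(m = model_pfm)),
               "non-empty")
})

test_that("target promoters are removed from an enclosing background", {
  set.seed(66)
  seqs <- stats::setNames(vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    character(1)), sprintf("g%02d", 1:30))
  all_prom <- promoter_set(seqs)
  target <- promoter_set(seqs[1:10])
  res <- motif_enrich(target, all_prom, list(ETSLIKE = planted_ets_pfm()))
  expect_equal(res$a + res$b, 10)
  expect_equal(res$c + res$d, 20)  # background minus target
})
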