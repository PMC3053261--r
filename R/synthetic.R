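D_ARCHETYPES <- c("down_sh_only", "up_both_only", "up_sh_only", "down_both_only",
                  "up_cyt_only", "down_cyt_only",
                  "singles_up_combo_null", "singles_down_combo_null")

# cell-mean log2 deltas (cyt, sh, both) per unit effect size for each
# interactive archetype; control cell is always 0
archetype_deltas <- function(arch, delta) {
  switch(arch,
         down_sh_only            = c(0, -delta, 0),
         up_both_only            = c(0, 0, delta),
         up_sh_only              = c(0, delta, 0),
         down_both_only          = c(0, 0, -delta),
         up_cyt_only             = c(delta, 0, 0),
         down_cyt_only           = c(-delta, 0, 0),
         singles_up_combo_null   = c(delta, delta, 0),
         singles_down_combo_null = c(-delta, -delta, 0),
         stop("unknown archetype: ", arch))
}

derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Configuration for the synthetic experiment generator
#'
#' Defaults emulate the scale of the modelled study: 14,220 genes in a
#' 2x2 design with 4 replicates per cell, category proportions echoing the
#' published summary tables, log-normal intensity noise, a 170-gene-scale
#' inflammatory set preferentially routed into two interactive archetypes, a
#' ChIP-style bound list of 1,219 genes enriched for knock-down-responsive
#' genes, and promoters with an ETS-like planted motif.
#'
#' @param n_genes number of genes.
#' @param category_props named proportions for categories `A`, `B`, `C`, `D`
#'   (remainder is `none`); must sum to at most 1.
#' @param effect_range range of |log2 fold change| for planted effects.
#' @param sigma residual standard deviation on the log2 scale.
#' @param replicates replicates per design cell (>= 2).
#' @param baseline_range range of baseline log2 intensities.
#' @param multi_probeset_rate fraction of genes carrying 2-3 probesets.
#' @param inflammatory_fraction fraction of genes in the inflammatory set.
#' @param metabolic_fraction fraction of genes in the metabolic set.
#' @param route_inflammatory fraction of inflammatory genes forced into the
#'   two interactive archetypes (`up_both_only`, `down_sh_only`).
#' @param bound_size size of the simulated bound-gene list (`NULL` scales
#'   1,219 by `n_genes / 14220`).
#' @param bound_odds_ratio sampling odds favouring factor-1-responsive genes
#'   in the bound list.
#' @param p_responsive,p_background motif planting probability in promoters
#'   of responsive vs non-responsive genes.
#' @param promoter_length promoter length in bases.
#' @param base_composition background base frequencies (A,C,G,T).
#' @param n_decoys number of decoy PFMs emitted alongside the planted motif.
#' @param seed master seed; all stage substreams derive from it.
#' @param fdr_calibration set `TRUE` when the bundle feeds FDR calibration
#'   tests; requires a nonzero null-category fraction.
#' @return `SimConfig` list.
#' @export
sim_config <- function(n_genes = 14220L,
                       category_props = c(A = 0.25, B = 0.045, C = 0.075, D = 0.035),
                       effect_range = c(0.8, 3),
                       sigma = 0.35,
                       replicates = 4L,
                       baseline_range = c(6, 12),
                       multi_probeset_rate = 0.1,
                       inflammatory_fraction = 0.012,
                       metabolic_fraction = 0.2,
                       route_inflammatory = 0.6,
                       bound_size = NULL,
                       bound_odds_ratio = 3,
                       p_responsive = 0.4,
                       p_background = 0.1,
                       promoter_length = 1500L,
                       base_composition = rep(0.25, 4),
                       n_decoys = 9L,
                       seed = 1L,
                       fdr_calibration = FALSE) {
  stopifnot(n_genes >= 1L, sigma > 0, replicates >= 2L,
            length(effect_range) == 2L, effect_range[1L] >= 0,
            effect_range[2L] >= effect_range[1L],
            all(category_props >= 0))
  if (!all(c("A", "B", "C", "D") %in% names(category_props)))
    stop("category_props must name A, B, C and D")
  if (sum(category_props) > 1 + 1e-12)
    stop("category proportions must sum to at most 1")
  if (fdr_calibration && sum(category_props) >= 1 - 1e-12)
    stop("FDR calibration requires a nonzero null-category fraction")
  if (is.null(bound_size)) bound_size <- round(1219 * n_genes / 14220)
  cfg <- list(n_genes = as.integer(n_genes), category_props = category_props,
              effect_range = effect_range, sigma = sigma,
              replicates = as.integer(replicates),
              baseline_range = baseline_range,
              multi_probeset_rate = multi_probeset_rate,
              inflammatory_fraction = inflammatory_fraction,
              metabolic_fraction = metabolic_fraction,
              route_inflammatory = route_inflammatory,
              bound_size = as.integer(bound_size),
              bound_odds_ratio = bound_odds_ratio,
              p_responsive = p_responsive, p_background = p_background,
              promoter_length = as.integer(promoter_length),
              base_composition = base_composition / sum(base_composition),
              n_decoys = as.integer(n_decoys),
              seed = as.integer(seed),
              fdr_calibration = fdr_calibration)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a 2x2 factorial expression experiment with known truth
#'
#' For each probeset of gene `g` and sample in cell `(i, j)` the log2 value
#' is `baseline + i b_sh + j b_cyt + i j b_int + e`, `e ~ N(0, sigma^2)`,
#' with `i, j` in `{0, 1}`; the matrix is emitted on the linear scale.
#' About `multi_probeset_rate` of genes carry 2-3 probesets sharing the
#' gene's effects. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (`ExpressionBundle`), `gene_map` (probeset to
#'   gene), and `truth` (data.frame: `gene_id`, `category`, `beta_sh`,
#'   `beta_cyt`, `beta_int`, `archetype`, `inflammatory`, `metabolic`,
#'   `bound`, `motif_planted` — the last two filled by the bound-list and
#'   promoter generators).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))

  props <- config$category_props[c("A", "B", "C", "D")]
  counts <- floor(props * n)
  category <- rep("none", n)
  pos <- 1L
  for (k in names(counts)) {
    if (counts[[k]] > 0L) {
      category[pos:(pos + counts[[k]] - 1L)] <- k
      pos <- pos + counts[[k]]
    }
  }

  # inflammatory genes: a routed share forced into the two focal interactive
  # archetypes, remainder spread over the other genes
  n_inflam <- max(1L, round(config$inflammatory_fraction * n))
  d_idx <- which(category == "D")
  n_routed <- min(round(config$route_inflammatory * n_inflam), length(d_idx))
  routed <- if (n_routed > 0L) sample(d_idx, n_routed) else integer(0L)
  others <- setdiff(seq_len(n), routed)
  free_inflam <- if (n_inflam - n_routed > 0L) sample(others, n_inflam - n_routed) else integer(0L)
  inflammatory <- seq_len(n) %in% c(routed, free_inflam)
  metabolic <- seq_len(n) %in%
    sample(seq_len(n), max(1L, round(config$metabolic_fraction * n)))

  draw_effect <- function(m) stats::runif(m, config$effect_range[1L], config$effect_range[2L])
  beta_sh <- beta_cyt <- beta_int <- numeric(n)
  archetype <- rep(NA_character_, n)

  idx_a <- which(category == "A")
  beta_sh[idx_a] <- draw_effect(length(idx_a)) * sample(c(-1, 1), length(idx_a), replace = TRUE)
  idx_b <- which(category == "B")
  beta_cyt[idx_b] <- draw_effect(length(idx_b)) * sample(c(-1, 1), length(idx_b), replace = TRUE)
  idx_c <- which(category == "C")
  beta_sh[idx_c] <- draw_effect(length(idx_c)) * sample(c(-1, 1), length(idx_c), replace = TRUE)
  beta_cyt[idx_c] <- draw_effect(length(idx_c)) * sample(c(-1, 1), length(idx_c), replace = TRUE)

  if (length(d_idx) > 0L) {
    archetype[d_idx] <- sample(D_ARCHETYPES, length(d_idx), replace = TRUE)
    archetype[routed] <- sample(c("up_both_only", "down_sh_only"),
                                length(routed), replace = TRUE)
    for (g in d_idx) {
      deltas <- archetype_deltas(archetype[[g]], draw_effect(1L))
      beta_cyt[g] <- deltas[[1L]]
      beta_sh[g] <- deltas[[2L]]
      beta_int[g] <- deltas[[3L]] - deltas[[1L]] - deltas[[2L]]
    }
  }

  # probesets: ~multi_probeset_rate of genes carry 2-3 probesets
  n_extra <- stats::rbinom(n, 1L, config$multi_probeset_rate) *
    sample(1:2, n, replace = TRUE)
  n_ps <- 1L + n_extra
  gene_of_ps <- rep(seq_len(n), n_ps)
  ps_ids <- sprintf("%s_ps%d", gene_ids[gene_of_ps],
                    unlist(lapply(n_ps, seq_len)))
  map <- stats::setNames(gene_ids[gene_of_ps], ps_ids)

  r <- config$replicates
  i_vec <- rep(c(0L, 0L, 1L, 1L), each = r)   # cells: ctrl, cyt, sh, both
  j_vec <- rep(c(0L, 1L, 0L, 1L), each = r)
  sample_ids <- sprintf("s%02d", seq_len(4L * r))
  design <- data.frame(sample_id = sample_ids,
                       factor1 = ifelse(i_vec == 1L, "treated", "control"),
                       factor2 = ifelse(j_vec == 1L, "treated", "control"),
                       replicate = rep(seq_len(r), times = 4L),
                       stringsAsFactors = FALSE)

  p <- length(ps_ids)
  baseline <- stats::runif(p, config$baseline_range[1L], config$baseline_range[2L])
  mean_log2 <- baseline +
    outer(beta_sh[gene_of_ps], i_vec) +
    outer(beta_cyt[gene_of_ps], j_vec) +
    outer(beta_int[gene_of_ps], i_vec * j_vec)
  log2_vals <- mean_log2 + matrix(stats::rnorm(p * 4L * r, 0, config$sigma), p, 4L * r)
  values <- 2^log2_vals
  dimnames(values) <- list(ps_ids, sample_ids)

  truth <- data.frame(gene_id = gene_ids, category = category,
                      beta_sh = beta_sh, beta_cyt = beta_cyt, beta_int = beta_int,
                      archetype = archetype,
                      inflammatory = inflammatory, metabolic = metabolic,
                      bound = NA, motif_planted = NA,
                      stringsAsFactors = FALSE)
  list(bundle = expression_bundle(values, design), gene_map = gene_map(map),
       truth = truth)
}

#' The planted ETS-like position frequency matrix
#'
#' Sharp 7-position PFM whose consensus is `CCGGAAG` with a secondary `A` at
#' the last position (the ELK1-style `CCGGAAG/A` site).
#' @return 4 x 7 count matrix.
#' @export
planted_ets_pfm <- function() {
  consensus <- c("C", "C", "G", "G", "A", "A")
  m <- matrix(0, 4L, 7L, dimnames = list(BASES, NULL))
  for (i in seq_along(consensus)) {
    m[, i] <- 1 / 3
    m[consensus[[i]], i] <- 97
  }
  m[, 7L] <- c(A = 40, C = 0, G = 57, T = 1)
  m
}

random_sharp_pfm <- function(length) {
  cons <- sample(BASES, length, replace = TRUE)
  m <- matrix(1 / 3, 4L, length, dimnames = list(BASES, NULL))
  for (i in seq_len(length)) m[cons[[i]], i] <- 97
  m
}

#' Simulate promoter sequences with a planted motif
#'
#' I.i.d. background sequence at the configured base composition; an
#' instance sampled from the planted PFM is inserted at a random position
#' with probability `p_responsive` in promoters of responsive (non-null)
#' genes and `p_background` otherwise. Decoy PFMs are emitted but never
#' planted.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_expression()].
#' @return list with `promoters` (`PromoterSet`), `pfms` (named list: the
#'   planted `ETSLIKE` motif first, then decoys), and `planted` (named
#'   logical per gene).
#' @export
simulate_promoters <- function(config, truth) {
  set.seed(derive_seed(config$seed, 2L))
  pfm <- planted_ets_pfm()
  if (ncol(pfm) > config$promoter_length)
    stop("motif longer than promoter")
  n <- nrow(truth)
  len <- config$promoter_length
  responsive <- truth$category != "none"
  p_plant <- ifelse(responsive, config$p_responsive, config$p_background)
  plant <- stats::runif(n) < p_plant

  base_mat <- matrix(sample(BASES, n * len, replace = TRUE,
                            prob = config$base_composition), n, len)
  seqs <- apply(base_mat, 1L, paste, collapse = "")
  col_prob <- sweep(pfm, 2L, colSums(pfm), "/")
  L <- ncol(pfm)
  model <- build_motif_model(pfm, background = config$base_composition,
                             name = "planted")
  draw_instance <- function() {
    # sampled from the PFM, conditioned on scoring as a site so a planted
    # promoter always contains a detectable instance
    for (try in 1:50) {
      inst <- paste(vapply(seq_len(L), function(i)
        sample(BASES, 1L, prob = col_prob[, i]), character(1L)), collapse = "")
      if (nrow(scan_motif(model, inst)) > 0L) return(inst)
    }
    model$consensus
  }
  for (g in which(plant)) {
    inst <- draw_instance()
    pos <- sample.int(len - L + 1L, 1L)
    substr(seqs[[g]], pos, pos + L - 1L) <- inst
  }
  names(seqs) <- truth$gene_id

  pfms <- c(list(ETSLIKE = pfm),
            stats::setNames(lapply(seq_len(config$n_decoys),
                                   function(i) random_sharp_pfm(sample(7:9, 1L))),
                            sprintf("DECOY%02d", seq_len(config$n_decoys))))
  list(promoters = promoter_set(seqs, window = "synthetic -1000/+500"),
       pfms = pfms,
       planted = stats::setNames(plant, truth$gene_id))
}

#' Simulate an external ChIP-style bound-gene list
#'
#' Samples genes without replacement with odds `bound_odds_ratio : 1`
#' favouring truly factor-1-responsive genes (categories A, C, D).
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_expression()].
#' @param size list size; defaults to `config$bound_size`.
#' @return character vector of bound gene ids (possibly empty).
#' @export
simulate_bound_list <- function(config, truth, size = config$bound_size) {
  set.seed(derive_seed(config$seed, 3L))
  n <- nrow(truth)
  if (size > n) stop("requested bound-list size exceeds gene count")
  if (size == 0L) return(character(0L))
  responsive1 <- truth$category %in% c("A", "C", "D")
  w <- ifelse(responsive1, config$bound_odds_ratio, 1)
  sample(truth$gene_id, size, prob = w)
}

#' Materialize gene sets from the truth table
#'
#' Emits the inflammatory set, plus 26 sets flagged as top-level
#' biological-process annotations: the metabolic set and 25 size-matched
#' random sets.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_expression()].
#' @return `GeneSetCollection` with 27 sets, 26 flagged top-level.
#' @export
simulate_gene_sets <- function(config, truth) {
  set.seed(derive_seed(config$seed, 4L))
  n <- nrow(truth)
  sets <- list(inflammatory_response = truth$gene_id[truth$inflammatory],
               metabolic_process = truth$gene_id[truth$metabolic])
  for (i in seq_len(25L)) {
    size <- max(5L, round(stats::runif(1L, 0.01, 0.25) * n))
    sets[[sprintf("process_%02d", i)]] <- sample(truth$gene_id, size)
  }
  gene_set_collection(sets, top_level = setdiff(names(sets), "inflammatory_response"))
}

#' Generate a complete synthetic input bundle
#'
#' Runs every generator stage from one config and attaches the bound and
#' motif-planted flags to the truth table.
#'
#' @param config a [sim_config()].
#' @return list with `bundle`, `gene_map`, `truth`, `promoters`, `pfms`,
#'   `gene_sets`, `bound`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  expr <- simulate_expression(config)
  prom <- simulate_promoters(config, expr$truth)
  bound <- simulate_bound_list(config, expr$truth)
  sets <- simulate_gene_sets(config, expr$truth)
  expr$truth$bound <- expr$truth$gene_id %in% bound
  expr$truth$motif_planted <- unname(prom$planted[expr$truth$gene_id])
  list(bundle = expr$bundle, gene_map = expr$gene_map, truth = expr$truth,
       promoters = prom$promoters, pfms = prom$pfms, gene_sets = sets,
       bound = bound)
}

#' Write a GeneSetCollection in GMT format
#' @param collection `GeneSetCollection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  top <- attr(collection, "top_level")
  lines <- vapply(names(collection), function(nm) {
    desc <- if (isTRUE(top[[nm]])) "top_level" else "set"
    paste(c(nm, desc, collection[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a full synthetic bundle to a directory of plain-text files
#'
#' Emits `matrix.tsv`, `samples.tsv`, `gene_map.tsv`, `sets.gmt`,
#' `promoters.fasta`, `motifs.pfm`, `bound.txt` and `truth.tsv`.
#'
#' @param bundle result of [simulate_bundle()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- data.frame(probeset_id = bundle$bundle$probeset_ids,
                    bundle$bundle$values, check.names = FALSE)
  utils::write.table(mat, file.path(dir, "matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$bundle$design, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(probeset_id = names(bundle$gene_map),
                                gene_id = unname(bundle$gene_map)),
                     file.path(dir, "gene_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets, file.path(dir, "sets.gmt"))
  write_fasta_promoters(bundle$promoters, file.path(dir, "promoters.fasta"))
  write_jaspar_pfm(bundle$pfms, file.path(dir, "motifs.pfm"))
  writeLines(bundle$bound, file.path(dir, "bound.txt"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
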