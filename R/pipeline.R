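#' Pipeline configuration
#'
#' One object holding every tunable of the end-to-end analysis. Defaults
#' reproduce the modelled study's printed settings: FDR 0.01, 2-fold filter,
#' cluster counts `{A:2, B:2, C:4, D:8}`, promoter window -1000/+500, score
#' cut-off 8.0, alpha 0.05 with Bonferroni correction over the gene-set and
#' motif families.
#'
#' @param synth a [sim_config()] generating the inputs, or `NULL` when
#'   `inputs` provides file paths.
#' @param inputs named list of paths (`matrix`, `samples`, `gene_map`,
#'   `gmt`, `promoters`, `pfms`, `bound`) read with the package readers;
#'   ignored when `synth` is given.
#' @param classify a [classify_config()].
#' @param k_map per-category cluster counts (must cover A, B, C, D).
#' @param alpha family-wise error rate for the enrichment scans.
#' @param score_cutoff per-window log2-ratio threshold for motif sites.
#' @param cluster_restarts K-means restarts per category.
#' @param seed master seed.
#' @return `PipelineConfig` list.
#' @export
pipeline_config <- function(synth = sim_config(), inputs = NULL,
                            classify = classify_config(),
                            k_map = default_k_map(),
                            alpha = 0.05, score_cutoff = 8.0,
                            cluster_restarts = 50L, seed = 1L) {
  if (is.null(synth) && is.null(inputs))
    stop("either a synth block or input paths are required")
  if (!all(c("A", "B", "C", "D") %in% names(k_map)))
    stop("k_map must cover categories A, B, C and D")
  structure(list(synth = synth, inputs = inputs, classify = classify,
                 k_map = k_map, alpha = alpha, score_cutoff = score_cutoff,
                 cluster_restarts = as.integer(cluster_restarts),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; a `synth` block
#' is passed to [sim_config()].
#'
#' @param path path to the YAML file.
#' @return `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth <- if (!is.null(y$synth)) do.call(sim_config, y$synth) else NULL
  cls <- if (!is.null(y$classify)) do.call(classify_config, y$classify)
         else classify_config()
  k_map <- if (!is.null(y$k_map)) unlist(y$k_map) else default_k_map()
  pipeline_config(synth = synth, inputs = y$inputs, classify = cls,
                  k_map = k_map,
                  alpha = if (is.null(y$alpha)) 0.05 else y$alpha,
                  score_cutoff = if (is.null(y$score_cutoff)) 8.0 else y$score_cutoff,
                  cluster_restarts = if (is.null(y$cluster_restarts)) 50L else y$cluster_restarts,
                  seed = if (is.null(y$seed)) 1L else y$seed)
}

load_inputs <- function(config) {
  if (!is.null(config$synth)) return(simulate_bundle(config$synth))
  p <- config$inputs
  bundle <- read_expression(p$matrix, p$samples)
  list(bundle = bundle,
       gene_map = read_gene_map(p$gene_map),
       truth = NULL,
       promoters = if (!is.null(p$promoters)) read_fasta_promoters(p$promoters) else NULL,
       pfms = if (!is.null(p$pfms)) read_jaspar_pfm(p$pfms) else NULL,
       gene_sets = if (!is.null(p$gmt)) read_gmt(p$gmt) else NULL,
       bound = if (!is.null(p$bound)) read_gene_list(p$bound) else NULL)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis end-to-end
#'
#' Stages, in order: ANOVA classification, probeset-to-gene collapse,
#' per-category K-means clustering, gene-set enrichment (inflammatory set
#' per cluster; top-level scan over the factor-1-responsive genes), overlap
#' with the external bound-gene list, and motif enrichment of responsive
#' promoters against the array background. Every output table is written
#' under `out_dir` with run metadata (seed, version, config hash); a rerun
#' into the same directory with a different configuration refuses to
#' overwrite unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the report tables, or `NULL` to skip
#'   writing.
#' @param force overwrite an out_dir produced by a different config.
#' @return list with `anova`, `calls`, `summary`, `shares`, `collapse`,
#'   `clusters`, `cluster_table`, `go_clusters`, `go_toplevel`, `overlap`,
#'   `motifs`, `config_hash`; invisibly when writing.
#' @export
run_pipeline <- function(config, out_dir = NULL, force = FALSE) {
  hash <- config_hash(unclass(config))
  if (!is.null(out_dir)) {
    stamp <- file.path(out_dir, "run_config_hash")
    if (file.exists(stamp) && !identical(readLines(stamp)[1], hash) && !force)
      stop("out_dir was produced by a different configuration; use force = TRUE")
  }

  data <- stage("load", load_inputs(config))
  message("stage classify: ", nrow(data$bundle$values), " probesets")
  records <- stage("classify", add_fdr(anova_two_way(data$bundle)))
  calls <- stage("classify", classify_probesets(records, config$classify))
  summary <- summarize_categories(calls)
  shares <- report_overlap_shares(summary)

  message("stage collapse")
  mean_int <- rowMeans(data$bundle$values)
  col <- stage("collapse", collapse_genes(calls, data$gene_map, mean_int))
  gene_calls <- col$gene_calls

  message("stage cluster")
  clusters <- stage("cluster",
                    cluster_categories(records, calls, config$k_map,
                                       seed = config$seed,
                                       n_restarts = config$cluster_restarts))
  cluster_table <- do.call(rbind, lapply(clusters, function(m)
    data.frame(probeset_id = names(m$assignments), category = m$category,
               cluster = unname(m$assignments), stringsAsFactors = FALSE)))
  if (is.null(cluster_table))
    cluster_table <- data.frame(probeset_id = character(0), category = character(0),
                                cluster = integer(0))

  universe <- gene_calls$gene_id
  gene_cat <- stats::setNames(gene_calls$category, gene_calls$gene_id)

  go_clusters <- NULL
  go_toplevel <- NULL
  if (!is.null(data$gene_sets)) {
    message("stage enrich")
    ps_gene <- stats::setNames(unname(data$gene_map[cluster_table$probeset_id]),
                               cluster_table$probeset_id)
    go_clusters <- stage("enrich", {
      out <- list()
      for (cat in names(clusters)) {
        m <- clusters[[cat]]
        for (cl in seq_len(m$k)) {
          ps <- names(m$assignments)[m$assignments == cl]
          genes <- intersect(unique(stats::na.omit(ps_gene[ps])), universe)
          genes <- genes[gene_cat[genes] == cat]  # collapse-retained, concordant
          if (length(genes) == 0L) next
          res <- enrich_sets(genes, data$gene_sets, universe, alpha = config$alpha,
                             correction = "none")
          res$category <- cat; res$cluster <- cl; res$n_genes <- length(genes)
          out[[paste(cat, cl)]] <- res
        }
      }
      do.call(rbind, out)
    })
    top_names <- names(attr(data$gene_sets, "top_level"))[attr(data$gene_sets, "top_level")]
    if (length(top_names) > 0L) {
      top_sets <- gene_set_collection(unclass(data$gene_sets)[top_names],
                                      top_level = top_names)
      resp1 <- universe[gene_cat[universe] %in% c("A", "C", "D")]
      go_toplevel <- stage("enrich",
                           enrich_sets(resp1, top_sets, universe,
                                       alpha = config$alpha,
                                       correction = "bonferroni"))
    }
  }

  overlap <- NULL
  if (!is.null(data$bound) && length(data$bound) > 0L) {
    message("stage overlap")
    resp1 <- universe[gene_cat[universe] %in% c("A", "C", "D")]
    bound <- intersect(data$bound, universe)
    overlap <- stage("overlap", overlap_analysis(bound, resp1, universe))
  }

  motifs <- NULL
  if (!is.null(data$promoters) && !is.null(data$pfms)) {
    message("stage motifs")
    resp1 <- universe[gene_cat[universe] %in% c("A", "C", "D")]
    target <- data$promoters[names(data$promoters) %in% resp1]
    motifs <- stage("motifs",
                    motif_enrich(promoter_set(unclass(target)[names(target)],
                                              window = attr(data$promoters, "window")),
                                 data$promoters, data$pfms,
                                 alpha = config$alpha,
                                 threshold = config$score_cutoff))
  }

  result <- list(anova = records, calls = calls, summary = summary,
                 shares = shares, collapse = col, clusters = clusters,
                 cluster_table = cluster_table, go_clusters = go_clusters,
                 go_toplevel = go_toplevel, overlap = overlap, motifs = motifs,
                 config_hash = hash, truth = data$truth)

  if (!is.null(out_dir)) {
    meta <- list(seed = config$seed, config_hash = hash)
    tables <- list(anova = records, category_calls = calls,
                   category_summary = summary, overlap_shares = shares,
                   gene_calls = gene_calls, dropped_genes = col$dropped,
                   cluster_assignments = cluster_table)
    if (!is.null(go_clusters)) tables$go_cluster_enrichment <- go_clusters
    if (!is.null(go_toplevel)) tables$go_toplevel_enrichment <- go_toplevel
    if (!is.null(overlap)) tables$bound_overlap <-
      cbind(overlap$result, share_bound = overlap$share1, share_de = overlap$share2)
    if (!is.null(motifs)) tables$motif_enrichment <- motifs
    write_results(tables, out_dir, metadata = meta)
    writeLines(hash, file.path(out_dir, "run_config_hash"))
    return(invisible(result))
  }
  result
}
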