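#!/usr/bin/env Rscript
# Gene-set enrichment: the inflammatory-response set tested in every
# expression cluster (one-tailed Fisher against the array universe), the
# 26-set top-level biological-process scan over knock-down-responsive genes
# with its Bonferroni cut-off, and the overlap between the external
# ChIP-style bound-gene list and the knock-down-responsive genes.

library(factorex)

bundle <- read_expression("results/bundle/matrix.tsv", "results/bundle/samples.tsv")
map <- read_gene_map("results/bundle/gene_map.tsv")
sets <- read_gmt("results/bundle/sets.gmt",
                 top_level = c("metabolic_process", sprintf("process_%02d", 1:25)))
bound <- read_gene_list("results/bundle/bound.txt")

records <- add_fdr(anova_two_way(bundle))
calls <- classify_probesets(records)
col <- collapse_genes(calls, map, rowMeans(bundle$values))
universe <- col$gene_calls$gene_id
gene_cat <- setNames(col$gene_calls$category, universe)
models <- cluster_categories(records, calls, seed = 1L)

inflam <- gene_set_collection(list(
  inflammatory_response = intersect(sets$inflammatory_response, universe)))
per_cluster <- do.call(rbind, lapply(names(models), function(cat) {
  m <- models[[cat]]
  do.call(rbind, lapply(seq_len(m$k), function(cl) {
    ps <- names(m$assignments)[m$assignments == cl]
    genes <- intersect(unique(unname(map[ps])), universe)
    genes <- genes[gene_cat[genes] == cat]
    if (length(genes) == 0) return(NULL)
    res <- enrich_sets(genes, inflam, universe, correction = "none")
    cbind(category = cat, cluster = cl, n_genes = length(genes), res)
  }))
}))
per_cluster <- per_cluster[order(per_cluster$p), ]

resp1 <- universe[gene_cat[universe] %in% c("A", "C", "D")]
top_sets <- gene_set_collection(unclass(sets)[names(sets) != "inflammatory_response"],
                                top_level = setdiff(names(sets), "inflammatory_response"))
toplevel <- enrich_sets(resp1, top_sets, universe, alpha = 0.05,
                        correction = "bonferroni")
overlap <- overlap_analysis(intersect(bound, universe), resp1, universe)

write_results(list(inflammatory_by_cluster = per_cluster,
                   go_toplevel = toplevel,
                   bound_overlap = cbind(overlap$result,
                                         share_bound = overlap$share1,
                                         share_de = overlap$share2)),
              "results/enrichment", metadata = list(seed = 1))

top <- per_cluster[1, ]
cat(sprintf("top inflammatory cluster: category %s cluster %d (%d genes, %.1fx expected, p = %.2g)\n",
            top$category, top$cluster, top$n_genes, top$fold_enrichment, top$p))
cat(sprintf("top-level scan: %d/26 sets below Bonferroni cut-off %.3g\n",
            sum(toplevel$significant), unique(toplevel$threshold)))
cat(sprintf("bound-list overlap: %.0f%% of bound genes responsive, %.0f%% of responsive bound (p = %.2g)\n",
            100 * overlap$share1, 100 * overlap$share2, overlap$result$p))
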