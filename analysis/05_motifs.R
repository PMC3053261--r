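#!/usr/bin/env Rscript
# Promoter motif analysis: every PFM is turned into a log2-ratio PWM
# (pseudocount spread by the background composition), promoters are
# classified by presence of at least one window scoring >= 8.0, and each
# motif's presence in knock-down-responsive promoters is tested against the
# array-wide background promoters with a one-tailed Fisher test under a
# Bonferroni cut-off over the motif family.

library(factorex)

bundle <- read_expression("results/bundle/matrix.tsv", "results/bundle/samples.tsv")
map <- read_gene_map("results/bundle/gene_map.tsv")
promoters <- read_fasta_promoters("results/bundle/promoters.fasta")
pfms <- read_jaspar_pfm("results/bundle/motifs.pfm")

records <- add_fdr(anova_two_way(bundle))
calls <- classify_probesets(records)
col <- collapse_genes(calls, map, rowMeans(bundle$values))
resp1 <- col$gene_calls$gene_id[col$gene_calls$category %in% c("A", "C", "D")]
target <- promoter_set(unclass(promoters)[intersect(resp1, names(promoters))])

enr <- motif_enrich(target, promoters, pfms, alpha = 0.05, threshold = 8.0)
write_results(list(motif_enrichment = enr), "results/motifs",
              metadata = list(seed = 1))

cat(sprintf("motifs tested: %d | Bonferroni cut-off %.2g\n",
            nrow(enr), unique(enr$threshold)))
top <- enr[1, ]
cat(sprintf("top motif: %s (%d/%d target vs %d/%d background promoters, p = %.2g)\n",
            top$set, top$a, top$a + top$b, top$c, top$c + top$d, top$p))
cat("significant motifs:", paste(enr$set[enr$significant], collapse = ", "), "\n")
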