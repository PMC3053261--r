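#!/usr/bin/env Rscript
# Generate the synthetic 2x2 factorial study bundle used by the downstream
# analysis steps: an HNF4-alpha-knock-down x cytokine design with 4
# replicates per cell, planted response categories, an inflammatory gene
# set routed into two interactive archetypes, a ChIP-style bound list, and
# promoters carrying a planted ETS-like motif. Scaled to 2,000 genes so the
# whole workflow reruns in minutes.

library(factorex)

out <- "results/bundle"
cfg <- sim_config(n_genes = 2000L, effect_range = c(2, 3), sigma = 0.25,
                  seed = 1L)
bun <- simulate_bundle(cfg)
write_bundle(bun, out)

cat("wrote synthetic bundle to", out, "\n")
cat("probesets:", length(bun$gene_map), " genes:", nrow(bun$truth), "\n")
print(table(bun$truth$category))
cat("inflammatory genes:", sum(bun$truth$inflammatory),
    "| bound genes:", length(bun$bound),
    "| promoters with planted motif:", sum(bun$truth$motif_planted), "\n")
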