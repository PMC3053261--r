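#!/usr/bin/env Rscript
# Two-way ANOVA classification of every probeset into the four response
# categories (A knock-down only, B cytokine only, C additive, D interactive)
# at FDR < 0.01, with the 2-fold filtered row and the overlap shares that
# summarize how much of the cytokine response is HNF4-alpha-dependent.

library(factorex)

bundle <- read_expression("results/bundle/matrix.tsv", "results/bundle/samples.tsv")
records <- add_fdr(anova_two_way(bundle))
calls <- classify_probesets(records, classify_config(alpha_fdr = 0.01,
                                                     fold_threshold = 2.0))
summary <- summarize_categories(calls)
shares <- report_overlap_shares(summary)

write_results(list(anova = records, category_calls = calls,
                   category_summary = summary, overlap_shares = shares),
              "results/classify", metadata = list(seed = 1))

cat("category counts (FDR < 0.01 / FDR + 2-fold):\n")
print(summary[, c("category", "n_fdr", "n_2fold")])
s <- shares$share_factor2_also_factor1
cat(sprintf("cytokine-responsive probesets also knock-down responsive: %.0f%% (FDR), %.0f%% (2-fold)\n",
            100 * s[1], 100 * s[2]))
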