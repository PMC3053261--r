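Package: factorex
Title: Two-Factor ANOVA Classification and Enrichment Analysis of
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 2x2 factorial perturbation experiments on
    expression microarrays, modelled on an HNF4-alpha knock-down by cytokine
    stimulation study in HepG2 cells. Classifies probesets by two-way ANOVA
    into single-factor, additive and interactive response categories with
    false-discovery-rate control, collapses probesets to genes, clusters
    group-mean profiles by K-means, tests gene-set and transcription-factor
    binding-site enrichment with one-tailed Fisher exact tests, and overlaps
    responsive genes with external ChIP-derived bound-gene lists. Includes a
    synthetic-data generator with known ground truth for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
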