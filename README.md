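# factorex

Analysis pipeline for balanced 2x2 factorial perturbation experiments on
expression microarrays, modelled on a classic design: knock-down of the
liver-enriched transcription factor HNF4-alpha crossed with proinflammatory
cytokine stimulation (IL-1-beta, IL-6, TNF-alpha) in HepG2 cells, four
replicate arrays per cell. The question the pipeline answers is how much of
the cytokine-driven acute-phase transcriptional program depends on
HNF4-alpha, and through which response shapes.

## What it computes

For each probeset, a fixed-effects two-way ANOVA on log2 intensities
decomposes the response into knock-down, cytokine and interaction effects
(`F = MS_effect / MS_E` on (1, 4(r-1)) df). Benjamini-Hochberg q-values per
effect family classify probesets at FDR < 0.01 into:

| Category | Definition |
|---|---|
| A | knock-down only (q_sh < alpha, others not) |
| B | cytokine only |
| C | additive — both main effects, no interaction |
| D | interactive — interaction q < alpha (dominates) |

Downstream: probesets collapse to genes (genes with discordant probesets
are dropped), z-scored group-mean profiles are clustered per category by
K-means (k = {A:2, B:2, C:4, D:8}, k-means++ with restarts), gene sets are
tested by one-tailed Fisher exact tests against the array universe
(hypergeometric upper tail, computed in log space; Bonferroni over the
26-set top-level scan), an external ChIP-style bound-gene list is overlapped
with the responsive genes, and promoters (-1 kb / +0.5 kb around the TSS)
are scanned with log2-ratio PWMs at a per-window cut-off of 8.0 for
presence-based motif enrichment against the array background.

A synthetic-data generator (`simulate_bundle()`) emits the full input
surface — expression matrix, sample sheet, gene map, GMT sets, promoters,
JASPAR-format PFMs, bound list — with a known truth table, so calibration
and recovery are measurable.

## Worked example

The numbered scripts under `analysis/` run the workflow on a seeded
synthetic study (2,000 genes, strong effects):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
Rscript analysis/03_collapse_cluster.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_motifs.R
```

`02_classify.R` prints the category table and the headline share:

```
category counts (FDR < 0.01 / FDR + 2-fold):
  category n_fdr n_2fold
1        A   593     590
2        B   109     107
3        C   174     174
4        D    77      74
5     none  1369       0
cytokine-responsive probesets also knock-down responsive: 70% (FDR), 70% (2-fold)
```

i.e. of the probesets responding to cytokines, 70% also respond to the
knock-down — the planted analogue of the published "over two thirds"
observation. `04_enrichment.R` then finds the planted inflammatory signal
and the bound-list overlap:

```
top inflammatory cluster: category D cluster 1 (17 genes, 39.1x expected, p = 2.7e-12)
bound-list overlap: 67% of bound genes responsive, 16% of responsive bound (p = 1.4e-17)
```

and `05_motifs.R` recovers the planted ETS-like motif (consensus
CCGGAAG/A) as the only significant matrix:

```
motifs tested: 10 | Bonferroni cut-off 0.005
top motif: ETSLIKE (407/724 target vs 496/1276 background promoters, p = 4.9e-14)
significant motifs: ETSLIKE
```

The same end-to-end run is available programmatically via
`run_pipeline(pipeline_config(synth = sim_config(...)), out_dir = "...")`,
which stamps every output table with the seed, package version and config
hash, and refuses to overwrite a directory produced by a different
configuration.

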