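---
title: "Classifying factorial expression responses: methods and design notes"
author: "factorex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying factorial expression responses: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experiment and the model

factorex analyses a balanced 2x2 factorial perturbation experiment on an
expression microarray: factor 1 is an shRNA knock-down of the transcription
factor HNF4-alpha, factor 2 is stimulation with a proinflammatory cytokine
mixture (IL-1-beta, IL-6, TNF-alpha), and each of the four cells carries
replicate arrays (four in the design the package emulates). Intensities
arrive already normalized on the linear scale; all inference happens on
`log2(intensity + 1)`.

For each probeset the package fits the classical fixed-effects two-way
ANOVA. Writing \(y_{ijk}\) for replicate \(k\) in cell \((i, j)\) with
\(i, j \in \{0, 1\}\),

\[ y_{ijk} = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + \varepsilon_{ijk},
   \qquad \varepsilon_{ijk} \sim N(0, \sigma^2), \]

and the orthogonal decomposition
\(SS_T = SS_A + SS_B + SS_{AB} + SS_E\) gives each effect an F statistic
\(MS_{\mathrm{eff}} / MS_E\) on \((1, 4(r-1))\) degrees of freedom. Because
the design is balanced the three contrasts are computed directly from the
cell means; unbalanced layouts are rejected rather than silently switching
to Type I/II/III sums of squares, since the modelled design is balanced and
the distinction would otherwise be invisible to the caller.

P-values are converted to q-values by the Benjamini-Hochberg step-up
procedure, applied separately within each of the three effect families
across all probesets. The original analysis states only "FDR < 0.01"
without naming a procedure; BH was the field default for microarray work of
that era, and `fdr_adjust()` is deliberately a thin, swappable wrapper.

## The four response categories

At a per-family FDR threshold `alpha_fdr` (default 0.01):

* **D "interactive"** — interaction q below threshold. The interaction
  dominates: a probeset with a significant interaction is D even when main
  effects are also significant, because "additive" is defined precisely by
  the absence of interaction, and interactive profiles can resemble
  main-effect profiles in their margins.
* **C "additive"** — both main effects significant, interaction not.
* **A "knock-down only"** / **B "cytokine only"** — exactly one main effect
  significant.
* **none** — everything else.

Directions are reported per significant main factor as the sign of that
factor's marginal log2 contrast. The fold change is the largest linear
ratio over the category-relevant contrasts: the factor-1 marginal for A,
the factor-2 marginal for B, the larger marginal for C. For D no single
contrast is canonical; the package uses the largest of the three
treated-cell versus control-cell contrasts, which tracks the visually
dominant excursion of interactive profiles. The "2-fold" summary row
counts the FDR-significant probesets whose category-relevant fold also
reaches the threshold (default 2.0).

Degenerate inputs are resolved deterministically: when the residual mean
square is exactly zero, an effect with zero sum of squares gets
\(F = 0, p = 1\) and a nonzero effect gets \(F = \infty, p = 0\).

## Gene collapsing

Probesets map many-to-one onto genes (Unigene-style). `collapse_genes()`
keeps a gene only when all of its probesets agree on the response pattern
— by default the category label; optionally category plus directions —
and drops disagreeing genes with reason `pattern-conflict`, so downstream
enrichment never counts an ambiguous gene. This is deliberately
conservative. The retained gene is represented by its probeset with the
highest mean intensity (deterministic, and the brightest probeset is
usually the best-measured one); unmapped probesets pass through as flagged
singleton pseudo-genes.

## Profile clustering

Within each category, each probeset's profile is its 4-vector of log2
group means in the fixed order (control, cytokines, shRNA,
shRNA+cytokines), z-scored per probeset with the population (n = 4)
standard deviation so that a non-constant profile has exactly unit
variance; constant profiles become all-zero vectors. Standardization makes
shape rather than magnitude the clustering signal, matching how the
category heat maps are read. Euclidean K-means with k-means++ seeding runs
`n_restarts` times (default 50, default seed 17) and keeps the lowest
inertia; cluster labels are then renumbered by descending cluster size
with ties broken by the smallest member index, because raw K-means label
order is an artifact of initialization. The per-category counts are fixed
at k = {A: 2, B: 2, C: 4, D: 8}; selecting k (gap statistic, silhouettes)
is out of scope.

## Enrichment statistics

All enrichment uses the one-tailed (over-representation) Fisher exact
test: the hypergeometric upper tail \(P(X \ge a)\) at fixed margins,
summed in log space from `lchoose` terms with a log-sum-exp, so p-values
far below 1e-100 retain full relative precision (and are available
unexponentiated via `log.p = TRUE`). Fold enrichment is
\((a / n_{\mathrm{target}}) / (K / N)\) with the expected count
\(n_{\mathrm{target}} K / N\).

The gene universe for set enrichment is all genes represented on the array
after collapse; annotation sets are intersected with the universe before
testing. The 26-set top-level biological-process scan applies Bonferroni
control, reporting the threshold at full precision (0.05 / 26 = 0.00192...)
and rounding to one significant digit for display.

Overlap with an external bound-gene list reports both conditional shares
(bound genes that respond; responding genes that are bound) plus the
Fisher p. Two table constructions are supported. The default
(`margin = "exclusive"`) keeps the four cells disjoint. The alternative
(`margin = "array"`) splits the bound genes by response but compares
against the whole array's response margin, re-counting the bound genes in
the comparison column; this looser construction is what reproduces the
published overlap p-value of the modelled study, so it is retained as an
explicit, documented option rather than a silent behaviour.

## Motif analysis

Promoters are fixed windows around the TSS — upstream 1000 bp and
downstream 500 bp by default, 0-based half-open, strand-aware, with an
extended 5000/2500 variant — clipped at contig ends with a warning. From a
JASPAR-style count matrix, column probabilities are
\((c_{b,i} + s \cdot q_b) / (\sum_b c_{b,i} + s)\) with total pseudocount
\(s = 4\) spread by the background composition \(q\) (one per base under a
uniform background), and PWM entries are \(\log_2(p_{b,i} / q_b)\). The
background composition defaults to the 0-order composition of the
background promoter set, configurable to uniform.

A site is any length-L window, on either strand, whose summed log2-ratio
score reaches the cut-off (default 8.0). Windows containing `N` score
\(-\infty\) and never match. The native Clover statistic is a
sequence-level averaged likelihood ratio; this package instead applies the
cut-off per window and then counts promoters containing at least one site,
which is simpler, deterministic, and consistent with the presence-based
Fisher step that follows. Presence calls are made in a single scan per
strand over the N-joined concatenation of the promoter set.

Motif enrichment compares presence in the target promoters against the
background promoters of all genes on the array; when the target is a
subset of the background, target promoters are removed from the background
so the 2x2 cells stay disjoint. Bonferroni control runs over the motif
family (about 140 JASPAR matrices reproduces the 3.5e-4-style cut-off).
When a TSS table offers several starts per gene, the most upstream TSS
would be used — one promoter per gene, deterministically.

## The synthetic-data generator

`simulate_bundle()` produces the complete input surface with known truth
so every stage has a parameter-recovery test. Its defaults are the
emulated study's conditions: 14,220 genes, 4 replicates per cell, category
proportions (A 25%, B 4.5%, C 7.5%, D 3.5%, rest null) echoing the
published summary tables, baseline log2 intensities uniform on [6, 12],
effect sizes |log2FC| uniform on [0.8, 3], and Normal noise on the log2
scale (log-normal intensities — the standard microarray error model; the
original analysis states none). Interactive genes draw one of eight
archetype shapes; two of them — induced only under the combined treatment,
and repressed only under knock-down alone — preferentially receive
inflammatory-set genes (60% routing) so the cluster-enrichment analysis
has a recoverable planted signal. The bound list samples genes with 3:1
odds favouring factor-1-responsive genes at the study-scale size of 1,219;
promoters are i.i.d. uniform-composition sequence with a sharp ETS-like
PFM (consensus CCGGAAG/A) planted at rate 0.4 in responsive versus 0.1 in
background promoters, alongside decoy PFMs that are never planted.
Planted instances are sampled from the PFM conditional on scoring as a
site, so a planted promoter always contains a detectable instance. A
single master seed feeds deterministic per-stage substreams.

What the generator does **not** emulate: probe-level effects, spatial or
batch artifacts, normalization residue, missing values, correlated genes,
heavy-tailed noise, or realistic promoter composition. Passing recovery
tests therefore demonstrates correctness of the inference machinery under
the generative model, not performance on real arrays.

## Problem sizes and calibration checks

The test suite and the analysis scripts run the generator scaled down —
2,000 genes for recovery and clustering checks, 5,000 all-null probesets
times 20 seeds for FDR calibration, 1,000 genes with 500 responsive
promoters for motif power, 20-50 seeds per simulation study — sizes chosen
so each check exercises the full pipeline while completing in minutes.
Under the all-null configuration the fraction of probesets assigned any
category at FDR < 0.01 stays below 2%; under strong effects (|log2FC| in
[2, 3], sigma = 0.25, r = 4) category recovery exceeds 95%; the planted
inflammatory archetype surfaces as the top-enriched cluster and the
planted motif ranks first among the PFMs in at least 90% of seeded runs.
These are the quantities `scripts/acceptance.R` recomputes.

## Known limitations

* Per-probeset variance is estimated with 12 residual degrees of freedom;
  no moderated (empirical-Bayes) variance shrinkage is applied, by design.
* The conservative collapse rule discards genuinely bimodal genes.
* K-means with fixed k inherits the original design's arbitrary cluster
  counts; cluster labels are comparable across reruns of this package but
  not to any external numbering.
* The per-window score cut-off diverges from Clover's sequence-level
  statistic; absolute hit counts are not comparable to Clover output.
* The generator's independence assumptions make calibration results an
  upper bound on real-data behaviour.
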