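---
title: "Methods: network-weighted candidate gene prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-weighted candidate gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtgminer)
```

## The problem

A QTL interval delimits tens to hundreds of genes; picking the causal one
usually requires years of fine mapping. `qtgminer` ranks interval genes by
how strongly they associate with *known* trait genes on a multi-omics
interaction network, moderated by transcriptome evidence from the mapping
population itself. This vignette documents the model, its assumptions, every
tunable that matters, and the deliberate numerical choices.

## The union network and its assumptions

The input network is an edge list with a layer label per edge (`chia_pet`,
`coexpression`, `cotranslation`, `ppi`). All distance and topology
computations run on the **union view**: a simple undirected graph with one
edge per unordered gene pair, however many layers support it. Two
assumptions are baked in:

* **Undirectedness.** Chromatin contacts and physical interactions have no
  canonical direction, and functional association is symmetric, so all
  layers are treated as undirected. Regulatory (directional) edge sets
  should be symmetrized before loading; this is an interpretation, not a
  theorem.
* **Unweighted hops.** No layer carries a confidence weight, so distances
  are unweighted hop counts. Layer labels are kept for provenance only.

Isolated genes are retained with all-zero topology rather than dropped, so
the gene universe (defined by the GFF3, not the network) stays stable across
the distance-based and the classifier-based rankers. Note the edge-list file
format can only carry edge-bearing nodes; un-networked genes rejoin the
universe through the gene models.

## The shortest-distance score

For query gene $g$ and positives $p_1,\dots,p_k$:

$$SD_g = \sum_i w(d(g, p_i)), \qquad w(1) = 1,\ w(2) = 0.01,\ w(\ge 3) = 0.$$

The 100:1 ratio means distance-2 contacts only ever tie-break among genes
with equal numbers of direct contacts (until 100 of them accumulate). Two
boundary rules are not dictated by the formula and were fixed here:

* a positive gene inside the interval contributes nothing to **its own**
  score ($d = 0$ is outside the two-layer scheme), avoiding
  self-reinforcement;
* positives absent from the network are silently unreachable, and query
  genes absent from the network score 0 with a warning — genes can
  legitimately be un-networked.

Evidence weighting rescales per interval: with $M = \max SD_g$ over the
interval's genes, $SD_d \in \{0, M\}$ flags differential expression and
$SD_v \in \{0, M/2, M\}$ flags major-effect variants in one or both of the
coding/UTR region classes, giving $SD_w = (SD_g + SD_d + SD_v)/3$. $M$ is
recomputed for every queried interval. When $M = 0$ (no interval gene within
two hops of any positive) the weights collapse to zero by construction; the
package warns and the classifier ranking should be used instead.

## Evidence profiles

A gene is differentially expressed iff its FDR-adjusted $q$ is **strictly**
below 0.05 (the threshold is a config value). Variant evidence admits 13
SnpEff effect terms: eleven protein-affecting terms (in-frame
insertions/deletions, frameshift, the three splice classes, start/stop
gains and losses) counted as *coding-region* evidence, and the two
`*_UTR_variant` terms as *UTR-region* evidence. `&`-composite SnpEff effects
are admitted when any component is admitted (recording the first admitted
component); multi-transcript annotations collapse to gene level with
any-transcript semantics. Presence of a qualifying variant in the supplied
VCF is taken as sufficient — no segregation test between specific lines is
attempted, since the VCF is expected to come from the contrasting pools
themselves.

## The classifier ranker

Features per gene, in fixed column order: 4 topology attributes, one capped
shortest distance per training gene (positives then negatives), then
$\log_2(\mathrm{TPM}+1)$ expression and translation columns. Distances are
clamped to `cap + 1` (default cap 6, so sentinel 7) for unreachable pairs,
absent targets, and paths longer than the cap — features must stay finite
and bounded for the classifiers. Missing genes in an omics matrix are
zero-imputed (and reported) rather than dropped.

Five algorithms are compared: bagged trees (`randomForest` with
`mtry = p`), XGBoost, ridge logistic regression (`glmnet`, $\alpha = 0$),
a single-hidden-layer neural network (`nnet`), and an RBF SVM with
probability calibration (`e1071`). Hyperparameters are pinned in
`qtg_config()` because reproducibility was preferred over fidelity to
unpublished originals:

| algorithm | defaults | note |
|---|---|---|
| neuralnet | 8 hidden units, decay 0.01, maxit 500 | see below |
| svm | RBF, cost 1 | features pre-standardized, `scale = FALSE` |
| xgboost | 200 rounds, depth 4, eta 0.3 | raw features |
| bagging | 100 trees, `mtry = p` | raw features |
| logistic | ridge, $\lambda$ = 0.01 | features pre-standardized |

The hidden layer is kept at 8 units deliberately: with ~140 inputs a wider
layer puts thousands of weights against fewer than a hundred training
genes — heavily overparameterized, and `nnet`'s BFGS optimizer scales
quadratically in weight count. Eight units with weight decay is the
classical regularized choice at this sample size.

Standardization (z-score) is fit on the training genes only and applied to
everything scored, for the three scale-sensitive algorithms; tree ensembles
consume raw features. Evaluation draws stratified 80/20 splits, reuses the
same splits across all five algorithms within a repeat (paired
comparisons), and repeats 20 times by default. `permute_labels = TRUE`
redraws a label permutation *within every repeat* — a fixed single
permutation retains chance overlap with the true module and biases the null
AUC away from 0.5; per-repeat permutation is the standard permutation-null
protocol and calibrates the mean to 0.5. All fits derive their seeds
deterministically from the one user seed.

The final probability ranking uses the neural network by default; its
probability enters $P_w = (P_n + P_d + P_v)/3$ with the same evidence
weights as above (unscaled: $P_n$ is already in $[0,1]$). The candidate-call
cutoff on $P_w$ is a config value (default 0.5) — it is a reporting
threshold, not part of the ranking.

## Combining the two rankings

The report joins the SD and ML rankings (which must cover the identical
interval gene set) by Borda count: `combined_rank` orders
`sd_rank + ml_rank`, ties broken by ascending gene ID, as are ties inside
each component ranking — every ordering in the package is deterministic.
Equal weighting of the two rankers is the documented default; the original
prioritization also folded in manual annotation review, which a program
cannot replicate, so annotation-relevant columns (`is_deg`,
`variant_class`) are surfaced in the report rather than scored. Interval
membership is any-overlap (≥ 1 bp), not containment: QTL boundaries are
imprecise.

## What the generator emulates — and what it does not

`simulate_bundle()` plants a partition: the positives form a dense module
(within-module edge probability 0.25 by default against a 0.01 background),
near-module genes on the QTL chromosome attach to ≥ 2 positives each, and
module + near genes share a rank-one expression factor over 31 expression
and 21 translation tissues — the configuration sizes match the reference
setting (32 + 55 training genes; 4 + 87 + 31 + 21 = 143 attributes).
Near genes are strongly enriched for DEG calls (80%) and both-region
variants (80%) against background rates of 10% each; training genes live on
other chromosomes, mimicking the realistic case where the interval contains
no already-known gene.

A planted-partition graph was chosen over a scale-free model because it
gives direct analytic control over the distance-1/2 positive counts that
drive $SD_g$. The cost is realism: real interaction networks have heavy
tailed degrees, the module structure of real trait genes is weaker and
overlapping, co-expression is confounded by tissue composition, and DEG and
variant evidence are correlated with network position in ways the generator
does not model. Passing the planted benchmark therefore demonstrates the
machinery is correct and the protocol calibrated — near-perfect AUCs on the
planted bundle say nothing quantitative about real-data AUCs.

## Numerical choices and degenerate inputs

* Eigenvector centrality is computed per connected component and
  max-normalized within it (tolerance 1e-10); isolated nodes get 0.
  Closeness is the within-component normalized form $(n_c - 1)/\sum d$.
* Sentinel distance `cap + 1` keeps feature matrices finite; the default
  cap of 6 covers the diameter range where guilt-by-association is
  informative.
* Ties everywhere break by ascending gene ID; reports are reproducible
  byte-for-byte under a fixed seed.
* Degenerate cases that are handled rather than rejected: $M = 0$ regions
  (warn, all-zero weights), constant feature columns (left unscaled),
  genes missing from network or omics matrices (zero-filled, flagged),
  empty variant tables (all $P_v = 0$).
* Problem sizes in the shipped tests: bundles of 120–400 genes,
  oracle-checked graphs up to 200 nodes, 20×5 evaluation on the default
  400-gene bundle — sizes at which every check re-runs comfortably on a
  laptop core.

## Known limitations

* Directionality of regulatory layers is discarded by design.
* The SD score ignores positive-set redundancy: five interchangeable
  paralogs at distance 1 count the same as five independent pathway members.
* Evidence weights are coarse (three levels) and treat all 13 variant
  classes as equally damaging.
* Classifier hyperparameters are pinned, not tuned per dataset; on real
  data a nested tuning loop may be warranted.
* The precomputed SD-table reader trusts the table's gene universe; it
  cannot validate distances it did not compute.
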