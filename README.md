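# qtgminer

Network-based prioritization of candidate causal genes in QTL intervals.

QTL mapping in a biparental population typically ends with an interval of a
few megabases containing tens to hundreds of genes, only one of which is the
quantitative trait gene (QTG). `qtgminer` ranks the genes of such an interval
by combining three lines of evidence:

1. **Guilt by association on a multi-omics network.** A layered interaction
   network (chromatin interaction / ChIA-PET, co-expression, co-translation,
   protein–protein interaction edges) is collapsed into a simple undirected
   union graph. For each interval gene the shortest-distance score sums a
   weight over the known trait genes (the "positives"):

   `SD_g = Σ_i [ 1 if d(g, p_i) = 1 ;  0.01 if d(g, p_i) = 2 ]`

   so direct neighbors of known trait genes dominate, two-hop neighbors
   contribute a hundredth, and everything further contributes nothing.

2. **Classifier probabilities.** Every gene gets 4 + |training genes| +
   |expression tissues| + |translation tissues| attributes — network
   topology (eccentricity, closeness, degree, eigenvector centrality),
   capped shortest distances to each positive and negative training gene,
   and log2(TPM+1) expression and translation profiles. Five classical
   classifiers (bagged trees, XGBoost, ridge logistic regression, a
   single-hidden-layer neural network, an RBF SVM) are compared by repeated
   stratified 80/20 holdout AUC; the neural network's probability `P_n` is
   used for ranking. With the reference configuration (32 + 55 training
   genes, 31 + 21 tissues) the matrix has the canonical 143 attributes.

3. **Per-gene evidence weights.** From a differential-expression table
   (`P_d = 1` if q < 0.05, else 0) and a SnpEff-annotated VCF restricted to
   13 major-effect variant classes (`P_v = 1` with variants in both coding
   and UTR regions, 0.5 with one, 0 with none). The two rankers weight these
   as

   `P_w = (P_n + P_d + P_v) / 3` and `SD_w = (SD_g + SD_d + SD_v) / 3`,

   where `SD_d`/`SD_v` are the same flags rescaled by the largest `SD_g` in
   the interval. The final report aggregates both rankings by Borda count.

A synthetic-data generator (`simulate_bundle()`) emits a complete,
deterministic input bundle — layered edge list, GFF3, training gene lists,
TPM matrices, DEG table, SnpEff-style VCF, truth table — with a planted
trait module, so the whole pipeline can be exercised and benchmarked
offline.

## Worked example

```r
library(qtgminer)

b      <- simulate_bundle(sim_config(seed = 1), "demo")
degs   <- call_degs(read_deg_table(b$paths$deg))
vars   <- parse_snpeff_vcf(b$paths$vcf, gene_universe = b$genes)
prof   <- build_profiles(degs, vars, b$genes)
region <- genes_in_interval(b$paths$gff, b$interval)

sd  <- score_region(region$id, b$train$positives, b$net, prof)
fm  <- build_features(b$net, b$train, b$expr, b$transl, b$genes)
pn  <- train_and_predict(fm, b$train, algorithm = "neuralnet", seed = 1)
pw  <- p_w(pn, prof, region$id)
head(as.data.frame(rank_candidates(sd, pw, profiles = prof)), 5)
```

```
   gene sd_w sd_rank   p_w ml_rank is_deg variant_class combined_rank
1 G0008 6.55       2 0.999       2   TRUE          both             1
2 G0066 7.23       1 0.999       3   TRUE          both             2
3 G0077 5.87       5 1.000       1   TRUE          both             3
4 G0041 6.02       4 0.833       5   TRUE           utr             4
5 G0045 6.02       3 0.833       6   TRUE           utr             5
```

The QTL interval holds 100 genes; the bundle's 8 "near-module" genes (here
G0008, G0040, G0041, G0045, G0062, G0066, G0077, G0090) are wired into the
planted trait module and enriched for DEG/variant evidence, and the report
recovers them at the top: high `sd_w` (many distance-1/2 positives), high
`p_w` (classifier probability plus evidence weights), low `combined_rank`
(sum of the two component ranks). Model comparison on the same bundle:

```r
summarize_models(evaluate_models(fm, b$train, repeats = 20, seed = 1))
```

```
            algorithm n_repeats mean_auc  sd_auc mean_auprc
1 logistic_regression        20    1.000 0.00000      1.000
2           neuralnet        20    1.000 0.00000      1.000
3                 svm        20    1.000 0.00000      1.000
4             bagging        20    0.999 0.00339      0.999
5             xgboost        20    0.964 0.05360      0.997
```

The planted module is deliberately well separated; on real networks AUCs
are lower and the spread between algorithms wider.

## Command line

The same pipeline is scriptable through the installed `cli/qtgminer`
entry point (or `qtgminer::qtg_cli()`):

```sh
qtgminer simulate  --out bundle --seed 3
qtgminer rank      --network bundle/network.tsv --positives bundle/positives.txt \
                   --negatives bundle/negatives.txt --expr bundle/expression_tpm.tsv \
                   --transl bundle/translation_tpm.tsv --gff bundle/genes.gff3 \
                   --region chr1:1-991000 --deg bundle/deg.tsv \
                   --vcf bundle/variants.vcf --seed 3 --out report.tsv
```

Every run writes a JSON manifest (command, flags, seed, config hash,
package version) beside its outputs.

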