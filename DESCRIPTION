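Package: qtgminer
Title: Network-Based Prioritization of Candidate Causal Genes in QTL Intervals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate causal genes inside quantitative trait locus
    (QTL) intervals by combining a guilt-by-association shortest-distance score
    on a multi-omics interaction network (chromatin interaction, co-expression,
    co-translation and protein-protein interaction layers), classical
    machine-learning classification over network topology, distance and
    expression attributes, and per-gene evidence weights from differential
    expression and major-effect sequence variants annotated by SnpEff. Includes
    a synthetic-data generator with a planted trait module so the full pipeline
    can be exercised and benchmarked offline, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    nnet,
    e1071,
    randomForest,
    xgboost,
    glmnet,
    pROC,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
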