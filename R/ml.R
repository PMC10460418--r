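ML_ALGORITHMS <- c("bagging", "xgboost", "logistic_regression", "neuralnet", "svm")

#' Assemble the gene-by-attribute feature matrix
#'
#' Concatenates, in fixed column order, (1) four topology attributes of the
#' union network (eccentricity, closeness, degree, eigenvector centrality),
#' (2) the capped shortest distance to every training gene (positives then
#' negatives, in list order), and (3) log2(TPM + 1) expression and translation
#' profiles across tissues. With 32 positive + 55 negative training genes and
#' 31 expression + 21 translation tissues this yields the canonical
#' 4 + 87 + 31 + 21 = 143 attributes. Genes absent from the network get
#' all-zero topology and sentinel distances; genes missing from an expression
#' matrix are zero-imputed and reported, so the full universe stays rankable.
#'
#' @param net a `qtg_network`.
#' @param train list with character vectors `positives` and `negatives`
#'   (disjoint, non-empty).
#' @param expr numeric matrix of TPM values, genes x tissues, with gene IDs as
#'   rownames; must be non-empty.
#' @param transl numeric matrix of TPM values, genes x tissues (translatome).
#' @param universe character vector of gene IDs to build rows for.
#' @param topo optional precomputed [node_topology()] table.
#' @param cap distance cap passed to [distances_to_set()].
#' @return numeric matrix, universe x attributes, with deterministic column
#'   names `eccentricity`, `closeness`, `degree`, `eigencentrality`,
#'   `d_to_<gene>`, `expr_<tissue>`, `transl_<tissue>`.
#' @export
build_features <- function(net, train, expr, transl, universe,
                           topo = NULL, cap = 6L) {
  stopifnot(inherits(net, "qtg_network"))
  universe <- as.character(universe)
  if (length(universe) == 0) stop("universe is empty")
  check_train(train)
  if (is.null(dim(expr)) || nrow(expr) == 0 || ncol(expr) == 0)
    stop("expression matrix is empty")
  missing_train <- setdiff(c(train$positives, train$negatives), universe)
  if (length(missing_train) > 0)
    warning(sprintf("%d training gene(s) absent from the universe: %s",
                    length(missing_train),
                    paste(utils::head(missing_train, 5), collapse = ", ")))

  if (is.null(topo)) topo <- node_topology(net)
  topo_cols <- c("eccentricity", "closeness", "degree", "eigencentrality")
  i <- match(universe, topo$gene)
  topo_block <- as.matrix(topo[ifelse(is.na(i), 1L, i), topo_cols, drop = FALSE])
  topo_block[is.na(i), ] <- 0  # un-networked genes: all-zero topology
  dimnames(topo_block) <- list(universe, topo_cols)

  targets <- c(train$positives, train$negatives)
  dist_all <- distances_to_set(net, targets, cap = cap)
  dist_block <- matrix(cap + 1, nrow = length(universe), ncol = length(targets),
                       dimnames = list(universe, paste0("d_to_", targets)))
  in_net <- universe %in% rownames(dist_all)
  dist_block[in_net, ] <- dist_all[universe[in_net], , drop = FALSE]
  # a gene absent from the network is at sentinel distance from everything but itself
  self_hit <- match(universe, targets)
  for (r in which(!in_net & !is.na(self_hit)))
    dist_block[r, self_hit[r]] <- 0

  expr_block <- expression_block(expr, universe, "expr_")
  transl_block <- expression_block(transl, universe, "transl_")

  cbind(topo_block, dist_block, expr_block, transl_block)
}

expression_block <- function(mat, universe, prefix) {
  if (is.null(dim(mat)) || ncol(mat) == 0)
    return(matrix(numeric(0), nrow = length(universe), ncol = 0,
                  dimnames = list(universe, NULL)))
  tissues <- colnames(mat)
  if (is.null(tissues)) tissues <- paste0("t", seq_len(ncol(mat)))
  i <- match(universe, rownames(mat))
  block <- matrix(0, nrow = length(universe), ncol = ncol(mat),
                  dimnames = list(universe, paste0(prefix, tissues)))
  hit <- !is.na(i)
  block[hit, ] <- log2(as.matrix(mat)[i[hit], , drop = FALSE] + 1)
  if (any(!hit))
    message(sprintf("build_features: %d gene(s) zero-imputed in %s block",
                    sum(!hit), sub("_$", "", prefix)))
  block
}

check_train <- function(train) {
  if (!is.list(train) || !all(c("positives", "negatives") %in% names(train)))
    stop("train must be a list with elements 'positives' and 'negatives'")
  if (length(train$positives) == 0 || length(train$negatives) == 0)
    stop("both training classes must be non-empty")
  overlap <- intersect(train$positives, train$negatives)
  if (length(overlap) > 0)
    stop("training classes overlap: ", paste(overlap, collapse = ", "))
  invisible(TRUE)
}

# z-score parameters fit on training rows only; constant columns left unscaled
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sd, "/")

SCALED_ALGOS <- c("neuralnet", "svm", "logistic_regression")

# Fit one classifier and return a prob-of-positive prediction closure.
fit_classifier <- function(algorithm, x, y, cfg, seed) {
  hp <- cfg$ml[[algorithm]]
  set.seed(seed)
  if (algorithm %in% SCALED_ALGOS) {
    sc <- fit_scaler(x)
    x <- apply_scaler(x, sc)
  }
  switch(algorithm,
    bagging = {
      fit <- randomForest::randomForest(x, as.factor(y), ntree = hp$ntree,
                                        mtry = ncol(x))
      function(newx) unname(stats::predict(fit, newx, type = "prob")[, "1"])
    },
    xgboost = {
      fit <- xgboost::xgb.train(
        params = list(max_depth = hp$max_depth, eta = hp$eta,
                      objective = "binary:logistic", nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = hp$nrounds)
      function(newx) unname(stats::predict(
        fit, xgboost::xgb.DMatrix(newx, nthread = 1)))
    },
    logistic_regression = {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = hp$lambda, standardize = FALSE)
      function(newx) as.numeric(stats::predict(
        fit, apply_scaler(newx, sc), type = "response"))
    },
    neuralnet = {
      fit <- nnet::nnet(x, y, size = hp$size, maxit = hp$maxit,
                        decay = hp$decay, entropy = TRUE, trace = FALSE,
                        MaxNWts = 100000)
      function(newx) as.numeric(stats::predict(fit, apply_scaler(newx, sc)))
    },
    svm = {
      fit <- e1071::svm(x, as.factor(y), kernel = hp$kernel, cost = hp$cost,
                        probability = TRUE, scale = FALSE)
      function(newx) {
        p <- stats::predict(fit, apply_scaler(newx, sc), probability = TRUE)
        unname(attr(p, "probabilities")[, "1"])
      }
    },
    stop("unknown algorithm: ", algorithm))
}

auprc <- function(labels, scores) {
  # average precision: mean precision at the rank of each true positive
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o] == 1
  if (!any(lab)) return(NA_real_)
  prec_at <- cumsum(lab) / seq_along(lab)
  mean(prec_at[lab])
}

roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' Evaluate the five classifiers by repeated stratified holdout
#'
#' Repeatedly splits the training genes into a stratified 80/20 partition,
#' fits each of five classical classifiers (bagged trees, gradient-boosted
#' trees, ridge-penalized logistic regression, a single-hidden-layer neural
#' network, and an RBF support-vector machine with probability calibration)
#' on the 80% and scores ROC AUC and area under the precision-recall curve
#' on the held-out 20%. The same splits are shared across algorithms within a
#' repeat so AUC comparisons are paired; everything is reproducible from the
#' seed.
#'
#' @param fm feature matrix from [build_features()].
#' @param train list with `positives` and `negatives` (each with at least 5
#'   genes present in `fm`).
#' @param repeats number of random splits (default 20).
#' @param holdout held-out fraction in (0, 1) (default 0.2).
#' @param seed integer seed controlling splits and model fits.
#' @param algorithms subset of the five algorithms to run.
#' @param cfg configuration list (see [qtg_config()]).
#' @param permute_labels if `TRUE`, the class labels are randomly re-permuted
#'   across the training genes within every repeat before splitting: the
#'   standard permutation null, which destroys the label-feature association
#'   while keeping class balance, so mean AUC calibrates to 0.5.
#' @return data.frame with columns `algorithm`, `repeat_index`, `auc`, `auprc`.
#' @export
evaluate_models <- function(fm, train, repeats = 20L, holdout = 0.2,
                            seed = 1L, algorithms = ML_ALGORITHMS,
                            cfg = qtg_config(), permute_labels = FALSE) {
  check_train(train)
  if (!(holdout > 0 && holdout < 1)) stop("holdout must be in (0, 1)")
  algorithms <- match.arg(algorithms, ML_ALGORITHMS, several.ok = TRUE)
  pos <- intersect(train$positives, rownames(fm))
  neg <- intersect(train$negatives, rownames(fm))
  if (length(pos) < 5 || length(neg) < 5)
    stop("need at least 5 genes per class in the feature matrix")
  x <- fm[c(pos, neg), , drop = FALSE]
  y <- c(rep(1, length(pos)), rep(0, length(neg)))

  # draw all stratified splits up-front so they are shared across algorithms
  set.seed(seed)
  n_test_pos <- max(1L, round(holdout * length(pos)))
  n_test_neg <- max(1L, round(holdout * length(neg)))
  splits <- lapply(seq_len(repeats), function(r) {
    yr <- if (permute_labels) sample(y) else y
    test <- c(sample(which(yr == 1), n_test_pos),
              sample(which(yr == 0), n_test_neg))
    list(train = setdiff(seq_along(yr), test), test = test, y = yr)
  })

  res <- list()
  for (r in seq_len(repeats)) {
    sp <- splits[[r]]
    for (ai in seq_along(algorithms)) {
      alg <- algorithms[ai]
      predict_fn <- fit_classifier(alg, x[sp$train, , drop = FALSE],
                                   sp$y[sp$train], cfg,
                                   seed = (seed %% 10000L) * 1000L + r * 10L + ai)
      p <- predict_fn(x[sp$test, , drop = FALSE])
      res[[length(res) + 1]] <- data.frame(
        algorithm = alg, repeat_index = r,
        auc = roc_auc(sp$y[sp$test], p),
        auprc = auprc(sp$y[sp$test], p),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Per-algorithm mean AUC / AUPRC summary
#' @param eval_tab output of [evaluate_models()].
#' @return data.frame with one row per algorithm, sorted by decreasing
#'   `mean_auc`.
#' @export
summarize_models <- function(eval_tab) {
  sp <- split(eval_tab, eval_tab$algorithm)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    algorithm = d$algorithm[1], n_repeats = nrow(d),
    mean_auc = mean(d$auc), sd_auc = stats::sd(d$auc),
    mean_auprc = mean(d$auprc), stringsAsFactors = FALSE)))
  out <- out[order(-out$mean_auc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit one classifier on all training genes and score the whole universe
#'
#' Fits the chosen algorithm (default: the neural network, the one used for
#' final prioritization) on every training gene and emits a probability of
#' being a trait gene, `p_n` in \[0,1\], for every gene in the feature
#' matrix. Training genes are scored too and flagged.
#'
#' @param fm feature matrix from [build_features()].
#' @param train training gene lists.
#' @param algorithm one of `bagging`, `xgboost`, `logistic_regression`,
#'   `neuralnet`, `svm`.
#' @param seed integer seed for the model fit.
#' @param cfg configuration list.
#' @return data.frame with columns `gene`, `p_n`, `is_training`.
#' @export
train_and_predict <- function(fm, train, algorithm = "neuralnet", seed = 1L,
                              cfg = qtg_config()) {
  check_train(train)
  algorithm <- match.arg(algorithm, ML_ALGORITHMS)
  bad_col <- which(!apply(is.finite(fm), 2, all))
  if (length(bad_col) > 0)
    stop("non-finite feature values in column(s): ",
         paste(colnames(fm)[utils::head(bad_col, 5)], collapse = ", "))
  pos <- intersect(train$positives, rownames(fm))
  neg <- intersect(train$negatives, rownames(fm))
  x <- fm[c(pos, neg), , drop = FALSE]
  y <- c(rep(1, length(pos)), rep(0, length(neg)))
  predict_fn <- fit_classifier(algorithm, x, y, cfg, seed = seed)
  p <- predict_fn(fm)
  data.frame(gene = rownames(fm), p_n = pmin(1, pmax(0, p)),
             is_training = rownames(fm) %in% c(pos, neg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Evidence-weighted probability score of region genes
#'
#' For each gene of a QTL region combines the classifier probability with the
#' DEG and variant evidence weights: `P_w = (P_n + P_d + P_v) / 3`, where
#' `P_d` is 1 for a DEG else 0 and `P_v` is 1 / 0.5 / 0 for variants in both /
#' one / no region class. Genes with no classifier score get `p_n = 0` with a
#' warning.
#'
#' @param scores data.frame from [train_and_predict()] (or any data.frame with
#'   `gene` and `p_n` columns).
#' @param profiles evidence profiles from [build_profiles()].
#' @param region_genes character vector of genes to score.
#' @return data.frame sorted by decreasing `p_w` (ties by ascending gene ID)
#'   with columns `gene`, `p_n`, `p_d`, `p_v`, `p_w`, `rank`.
#' @export
p_w <- function(scores, profiles, region_genes) {
  region_genes <- as.character(region_genes)
  if (length(region_genes) == 0) stop("region gene list is empty")
  i <- match(region_genes, scores$gene)
  if (any(is.na(i)))
    warning(sprintf("%d region gene(s) without a classifier score get p_n = 0",
                    sum(is.na(i))))
  p_n <- ifelse(is.na(i), 0, scores$p_n[i])
  j <- match(region_genes, profiles$gene)
  p_d <- ifelse(is.na(j), 0, profiles$p_d[j])
  p_v <- ifelse(is.na(j), 0, profiles$p_v[j])
  out <- data.frame(gene = region_genes, p_n = p_n, p_d = p_d, p_v = p_v,
                    p_w = (p_n + p_d + p_v) / 3, stringsAsFactors = FALSE)
  out <- out[order(-out$p_w, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
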