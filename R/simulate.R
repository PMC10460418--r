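#' Simulation configuration
#'
#' Parameters of the synthetic multi-omics bundle. The defaults mirror the
#' data regime the method was designed for: 32 positive and 55 negative
#' training genes, expression over 31 tissues/stages and translation over 21
#' tissues/stages, a dense planted trait module among the positives, and a
#' QTL chromosome whose "near-module" genes carry elevated network, DEG and
#' variant signal.
#'
#' @param n_genes total genes in the universe.
#' @param n_positive size of the planted trait module (the positive training
#'   set and the guilt-by-association positives).
#' @param n_negative curated negative training genes.
#' @param module_edge_prob within-module edge probability; must exceed
#'   `background_edge_prob`.
#' @param background_edge_prob Erdos-Renyi background edge probability.
#' @param n_expr_tissues,n_transl_tissues tissue counts of the expression and
#'   translation matrices.
#' @param deg_fraction background probability that a gene is differentially
#'   expressed.
#' @param variant_rate background probability that a gene carries one admitted
#'   major-effect variant.
#' @param n_qtl_genes genes placed on the QTL chromosome (`chr1`).
#' @param n_near near-module genes inside the QTL interval: each is wired to
#'   at least two module genes and enriched for DEG/variant evidence.
#' @param near_edge_prob per-positive edge probability of a near-module gene.
#' @param seed integer RNG seed; identical seeds give byte-identical bundles.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 400L, n_positive = 32L, n_negative = 55L,
                       module_edge_prob = 0.25, background_edge_prob = 0.01,
                       n_expr_tissues = 31L, n_transl_tissues = 21L,
                       deg_fraction = 0.1, variant_rate = 0.1,
                       n_qtl_genes = 100L, n_near = 8L, near_edge_prob = 0.15,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              module_edge_prob = module_edge_prob,
              background_edge_prob = background_edge_prob,
              n_expr_tissues = as.integer(n_expr_tissues),
              n_transl_tissues = as.integer(n_transl_tissues),
              deg_fraction = deg_fraction, variant_rate = variant_rate,
              n_qtl_genes = as.integer(n_qtl_genes), n_near = as.integer(n_near),
              near_edge_prob = near_edge_prob, seed = as.integer(seed))
  probs <- c(cfg$module_edge_prob, cfg$background_edge_prob,
             cfg$deg_fraction, cfg$variant_rate, cfg$near_edge_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$module_edge_prob <= cfg$background_edge_prob)
    stop("module_edge_prob must exceed background_edge_prob (no planted signal)")
  if (cfg$n_positive + cfg$n_negative >= cfg$n_genes)
    stop("n_positive + n_negative must be smaller than n_genes")
  if (choose(cfg$n_positive, 2) * cfg$module_edge_prob < 1)
    stop("infeasible config: expected module edge count below 1")
  if (cfg$n_near >= cfg$n_qtl_genes)
    stop("n_near must be smaller than n_qtl_genes")
  structure(cfg, class = "sim_config")
}

# deterministic pair decoding for Erdos-Renyi sampling: k-th unordered pair
pair_from_index <- function(k, n) {
  # row i satisfies cum(i) >= k where cum(i) = i*n - i*(i+1)/2
  i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * k)) / 2)
  j <- k - ((i - 1) * n - i * (i - 1) / 2) + i
  cbind(i, j)
}

#' Generate a synthetic multi-omics bundle with a planted trait module
#'
#' Emits, to `out_dir`, every input the pipeline consumes: a layered network
#' edge list, a GFF3 of gene models on five chromosomes, positive and
#' negative training gene lists, TPM expression and translation matrices,
#' a DEG table, a SnpEff-annotated VCF, a QTL interval table and a truth
#' table. The positives form a dense planted module and share a low-rank
#' expression program; near-module genes on the QTL chromosome are wired into
#' the module and enriched for DEG and variant evidence, so every downstream
#' ranker has recoverable signal. Identical seeds give identical bundles.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the file `paths`, the `truth` table, the
#'   interval spec string and the in-memory pieces of the bundle.
#' @export
simulate_bundle <- function(cfg = sim_config(), out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_qtl <- cfg$n_qtl_genes
  chrom <- c(rep("chr1", n_qtl),
             paste0("chr", 2 + (seq_len(cfg$n_genes - n_qtl) - 1) %% 4))
  idx_on_chrom <- stats::ave(seq_len(cfg$n_genes), chrom, FUN = seq_along)
  start <- (idx_on_chrom - 1) * 10000L + 1001L
  end <- start + 2999L
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)

  off_qtl <- genes[chrom != "chr1"]
  positives <- sort(sample(off_qtl, cfg$n_positive))
  negatives <- sort(sample(setdiff(off_qtl, positives), cfg$n_negative))
  near <- sort(sample(genes[chrom == "chr1"], cfg$n_near))
  role <- rep("background", cfg$n_genes)
  names(role) <- genes
  role[positives] <- "positive"
  role[negatives] <- "negative"
  role[near] <- "near"

  ## network: planted module + near-gene wiring + Erdos-Renyi background
  edges <- list()
  mod_pairs <- utils::combn(positives, 2)
  keep <- stats::runif(ncol(mod_pairs)) < cfg$module_edge_prob
  edges$module <- data.frame(gene_a = mod_pairs[1, keep],
                             gene_b = mod_pairs[2, keep],
                             stringsAsFactors = FALSE)
  near_edges <- do.call(rbind, lapply(near, function(g) {
    k <- max(2L, stats::rbinom(1, cfg$n_positive, cfg$near_edge_prob))
    data.frame(gene_a = g, gene_b = sample(positives, k),
               stringsAsFactors = FALSE)
  }))
  edges$near <- near_edges
  n_pairs <- choose(cfg$n_genes, 2)
  k_bg <- stats::rbinom(1, n_pairs, cfg$background_edge_prob)
  bg_idx <- sort(sample.int(n_pairs, k_bg))
  ij <- pair_from_index(bg_idx, cfg$n_genes)
  edges$background <- data.frame(gene_a = genes[ij[, 1]], gene_b = genes[ij[, 2]],
                                 stringsAsFactors = FALSE)
  edge_tab <- do.call(rbind, edges)
  edge_tab$layer <- sample(NETWORK_LAYERS, nrow(edge_tab), replace = TRUE)
  net <- suppressMessages(network_from_edges(edge_tab, extra_nodes = genes))

  ## expression / translation: shared low-rank program for module + near genes
  signal_genes <- c(positives, near)
  make_tpm <- function(n_tissues, prefix) {
    f <- stats::rnorm(n_tissues)
    lambda <- stats::setNames(rep(0, cfg$n_genes), genes)
    lambda[signal_genes] <- stats::runif(length(signal_genes), 0.8, 1.2)
    base <- matrix(stats::rnorm(cfg$n_genes * n_tissues, mean = 2, sd = 0.8),
                   nrow = cfg$n_genes)
    x <- base + outer(lambda, f)
    tpm <- round(2^x, 3)
    dimnames(tpm) <- list(genes, paste0(prefix, seq_len(n_tissues)))
    tpm
  }
  expr <- make_tpm(cfg$n_expr_tissues, "tissue")
  transl <- make_tpm(cfg$n_transl_tissues, "stage")

  ## DEG evidence: near-module genes strongly enriched
  p_deg <- ifelse(role %in% c("near"), 0.8, cfg$deg_fraction)
  is_deg_true <- stats::runif(cfg$n_genes) < p_deg
  q <- ifelse(is_deg_true, stats::runif(cfg$n_genes, 0, 0.049),
              stats::runif(cfg$n_genes, 0.05, 1))
  deg_tab <- data.frame(gene = genes,
                        log2fc = round(stats::rnorm(cfg$n_genes, 0,
                                                    ifelse(is_deg_true, 2, 0.5)), 4),
                        q = round(q, 6), stringsAsFactors = FALSE)

  ## variants: near genes mostly hit in both coding and UTR regions
  coding_terms <- setdiff(ADMITTED_EFFECTS, UTR_EFFECTS)
  var_rows <- list()
  vclass <- rep("none", cfg$n_genes)
  names(vclass) <- genes
  for (g in genes) {
    if (role[g] == "near") {
      cls <- if (stats::runif(1) < 0.8) "both" else sample(c("coding", "utr"), 1)
    } else {
      cls <- if (stats::runif(1) < cfg$variant_rate)
        sample(c("coding", "utr"), 1) else "none"
    }
    vclass[g] <- cls
    effs <- switch(cls,
                   none = character(),
                   coding = sample(coding_terms, 1),
                   utr = sample(UTR_EFFECTS, 1),
                   both = c(sample(coding_terms, 1), sample(UTR_EFFECTS, 1)))
    if (length(effs) > 0)
      var_rows[[g]] <- data.frame(gene = g, effect = effs,
                                  stringsAsFactors = FALSE)
  }
  var_tab <- do.call(rbind, c(var_rows,
                              list(data.frame(gene = character(),
                                              effect = character()))))

  truth <- data.frame(gene = genes, chrom = chrom, role = unname(role),
                      is_deg = unname(is_deg_true),
                      variant_class = unname(vclass),
                      stringsAsFactors = FALSE)
  interval <- sprintf("chr1:1-%d", max(end[chrom == "chr1"]))

  ## write the bundle
  paths <- list(
    network = file.path(out_dir, "network.tsv"),
    gff = file.path(out_dir, "genes.gff3"),
    positives = file.path(out_dir, "positives.txt"),
    negatives = file.path(out_dir, "negatives.txt"),
    expr = file.path(out_dir, "expression_tpm.tsv"),
    transl = file.path(out_dir, "translation_tpm.tsv"),
    deg = file.path(out_dir, "deg.tsv"),
    vcf = file.path(out_dir, "variants.vcf"),
    intervals = file.path(out_dir, "intervals.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_network(net, paths$network)
  write_gff3(data.frame(id = genes, chrom = chrom, start = start, end = end,
                        strand = strand, stringsAsFactors = FALSE), paths$gff)
  writeLines(positives, paths$positives)
  writeLines(negatives, paths$negatives)
  write_matrix_tsv(expr, paths$expr)
  write_matrix_tsv(transl, paths$transl)
  utils::write.table(deg_tab, paths$deg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gene_pos <- stats::setNames(start, genes)
  gene_chrom <- stats::setNames(chrom, genes)
  write_snpeff_vcf(var_tab, gene_chrom, gene_pos, paths$vcf)
  utils::write.table(
    data.frame(name = "qQTL1-1", chrom = "chr1", start = 1L,
               end = max(end[chrom == "chr1"])),
    paths$intervals, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(paths = paths, truth = truth, interval = interval,
                 net = net, expr = expr, transl = transl, deg = deg_tab,
                 variants = var_tab,
                 train = list(positives = positives, negatives = negatives),
                 near = near, genes = genes, config = cfg))
}

write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-tissue TPM matrix from TSV
#'
#' First column = gene ID, remaining columns = tissues.
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  m
}

write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tqtgminer_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     models$chrom, models$start, models$end, models$strand,
                     models$id))
  writeLines(lines, path)
  invisible(path)
}

# SnpEff-style VCF emitter for the synthetic bundle: one record per variant,
# ANN INFO field with effect in subfield 2 and gene ID in subfields 4/5.
write_snpeff_vcf <- function(var_tab, gene_chrom, gene_pos, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=qtgminer_sim",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele | Annotation | Annotation_Impact | Gene_Name ",
           "| Gene_ID | Feature_Type | Feature_ID | Transcript_BioType | Rank ",
           "| HGVS.c | HGVS.p | cDNA.pos | CDS.pos | AA.pos | Distance | ",
           "ERRORS'\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(var_tab) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  impact <- ifelse(var_tab$effect %in% UTR_EFFECTS, "MODIFIER", "HIGH")
  ann <- sprintf(
    "T|%s|%s|%s|%s|transcript|%s_T001|protein_coding|1/1|c.1A>T|p.?|||||",
    var_tab$effect, impact, var_tab$gene, var_tab$gene, var_tab$gene)
  pos <- gene_pos[var_tab$gene] + 50L + seq_len(nrow(var_tab)) %% 100L
  body <- sprintf("%s\t%d\tvar%04d\tA\tT\t50\tPASS\tANN=%s",
                  gene_chrom[var_tab$gene], pos, seq_len(nrow(var_tab)), ann)
  # VCF records must be position-sorted within chromosome
  o <- order(gene_chrom[var_tab$gene], pos)
  writeLines(c(header, body[o]), path)
  invisible(path)
}
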