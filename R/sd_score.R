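#' Guilt-by-association shortest-distance score
#'
#' For each query gene, sums a weight over the known positive (trait) genes:
#' 1 for every positive at hop distance 1 on the union network and 0.01 for
#' every positive at hop distance 2; positives further away contribute 0.
#' A query gene that is itself positive contributes nothing to its own score
#' (self-distance 0 falls outside the two-layer scheme). Positives not present
#' in the network are ignored; query genes absent from the network score 0
#' with a warning, since genes can legitimately be un-networked.
#'
#' @param genes character vector of query gene IDs.
#' @param positives non-empty character vector of known trait genes.
#' @param net a `qtg_network`.
#' @return named numeric vector of SD_g scores, one per query gene.
#' @export
sd_g <- function(genes, positives, net) {
  stopifnot(inherits(net, "qtg_network"))
  genes <- as.character(genes)
  if (length(positives) == 0) stop("positive gene set is empty")
  pos_in <- unique(as.character(positives))
  pos_in <- pos_in[pos_in %in% net$nodes]
  out <- stats::setNames(numeric(length(genes)), genes)
  absent <- !(genes %in% net$nodes)
  if (any(absent))
    warning(sprintf("%d query gene(s) absent from the network score 0: %s",
                    sum(absent), paste(utils::head(genes[absent], 5), collapse = ", ")))
  present <- unique(genes[!absent])
  if (length(present) == 0 || length(pos_in) == 0) return(out)
  d <- igraph::distances(net$graph, v = present, to = pos_in)
  score <- rowSums(d == 1) * 1 + rowSums(d == 2) * 0.01
  out[!absent] <- score[genes[!absent]]
  out
}

#' Score and rank the genes of a QTL region by weighted shortest distance
#'
#' Computes SD_g for every region gene, then the region maximum
#' `M = max(SD_g)`, and per gene the evidence-weighted components:
#' `SD_d = M` for a differentially expressed gene, else 0; `SD_v = M` for a
#' gene with admitted variants in both coding and UTR regions, `M/2` for one
#' region, else 0. The weighted score is `SD_w = (SD_g + SD_d + SD_v) / 3`.
#' When no region gene lies within two hops of any positive (`M = 0`) the
#' evidence weights collapse to zero by construction and a warning suggests
#' the probability-based ranker instead.
#'
#' @param region_genes non-empty character vector of gene IDs in the interval.
#' @param positives known trait genes (see [sd_g()]).
#' @param net a `qtg_network`.
#' @param profiles evidence profiles from [build_profiles()]; genes missing
#'   from it are treated as evidence-free.
#' @return data.frame sorted by decreasing `sd_w` (ties broken by ascending
#'   gene ID) with columns `gene`, `sd_g`, `sd_d`, `sd_v`, `sd_w`, `rank`.
#' @export
score_region <- function(region_genes, positives, net, profiles = NULL) {
  region_genes <- as.character(region_genes)
  if (length(region_genes) == 0) stop("region gene list is empty")
  g <- sd_g(region_genes, positives, net)
  m <- max(g)
  if (m == 0)
    warning("no region gene is within two hops of any positive gene (M = 0); ",
            "evidence weights are inert - consider the ML ranker")
  if (is.null(profiles)) {
    is_deg <- rep(FALSE, length(region_genes))
    pv <- rep(0, length(region_genes))
  } else {
    i <- match(region_genes, profiles$gene)
    is_deg <- ifelse(is.na(i), FALSE, profiles$is_deg[i])
    pv <- ifelse(is.na(i), 0, profiles$p_v[i])
  }
  sd_d <- ifelse(is_deg, m, 0)
  sd_v <- pv * m  # p_v in {0, 0.5, 1} maps to {0, M/2, M}
  sd_w <- (g + sd_d + sd_v) / 3
  out <- data.frame(gene = region_genes, sd_g = as.numeric(g),
                    sd_d = sd_d, sd_v = sd_v, sd_w = sd_w,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sd_w, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
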