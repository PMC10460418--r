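# Independent oracles and fixture builders. Everything here avoids the
# package's own graph machinery (igraph): adjacency lists + hand-rolled BFS,
# so engine results are checked against a second, independent route.

# adjacency list (named list of character vectors) from an edge data.frame
adj_list <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b, nodes)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character()
  for (k in seq_len(nrow(edges))) {
    a <- edges$gene_a[k]; b <- edges$gene_b[k]
    if (a == b) next
    if (!b %in% adj[[a]]) adj[[a]] <- c(adj[[a]], b)
    if (!a %in% adj[[b]]) adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# plain queue BFS; returns named integer distances (Inf when unreachable)
bfs_dist <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[v] + 1
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  d
}

# literal two-layer summation over positives: 1 per distance-1, 0.01 per
# distance-2 positive
sd_g_oracle <- function(edges, genes, positives, nodes = NULL) {
  adj <- adj_list(edges, nodes)
  positives <- intersect(positives, names(adj))
  out <- stats::setNames(numeric(length(genes)), genes)
  for (g in genes) {
    if (!g %in% names(adj)) next
    d <- bfs_dist(adj, g)[positives]
    out[g] <- sum(d == 1) + 0.01 * sum(d == 2)
  }
  out
}

# max-normalized eigenvector centrality by plain power iteration on the
# component's adjacency matrix
eigen_oracle <- function(edges, nodes) {
  adj <- adj_list(edges, nodes)
  nodes <- names(adj)
  a <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (v in nodes) a[v, adj[[v]]] <- 1
  out <- stats::setNames(numeric(length(nodes)), nodes)
  seen <- character()
  for (v in nodes) {
    if (v %in% seen) next
    comp <- names(which(is.finite(bfs_dist(adj, v))))
    seen <- c(seen, comp)
    if (length(comp) == 1) next
    m <- a[comp, comp]
    x <- rep(1, length(comp))
    for (i in 1:2000) {
      x2 <- as.vector(m %*% x)
      x2 <- x2 / sqrt(sum(x2^2))
      if (max(abs(x2 - x)) < 1e-12) break
      x <- x2
    }
    out[comp] <- x / max(x)
  }
  out
}

# Erdos-Renyi edge table over toy gene IDs
random_edges <- function(n, p, prefix = "N") {
  nodes <- sprintf("%s%03d", prefix, seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# small planted-partition edge table: dense block among `n_mod` module nodes
planted_edges <- function(n, n_mod, p_in = 0.4, p_out = 0.03) {
  nodes <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  in_mod <- pairs[1, ] %in% nodes[1:n_mod] & pairs[2, ] %in% nodes[1:n_mod]
  keep <- stats::runif(ncol(pairs)) < ifelse(in_mod, p_in, p_out)
  list(edges = data.frame(gene_a = pairs[1, keep], gene_b = pairs[2, keep],
                          stringsAsFactors = FALSE),
       nodes = nodes, module = nodes[1:n_mod])
}

make_net <- function(edges, extra_nodes = character()) {
  suppressMessages(network_from_edges(edges, extra_nodes = extra_nodes))
}

# minimal SnpEff-style VCF writer driven by explicit ANN strings
write_ann_vcf <- function(path, ann_strings, chrom = "chr1") {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\tA\tT\t50\tPASS\t%s", chrom,
                  1000L + seq_along(ann_strings) * 10L, ann_strings)
  writeLines(c(header, body), path)
  path
}

ann_entry <- function(gene, effect) {
  sprintf("ANN=T|%s|HIGH|%s|%s|transcript|%s_T001|protein_coding|1/1|c.1A>T|p.?|||||",
          effect, gene, gene, gene)
}

# tiny GFF3 writer
write_test_gff <- function(path, models) {
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       models$chrom, models$start, models$end,
                       models$strand, models$id)), path)
  path
}
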