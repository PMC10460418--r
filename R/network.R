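#' @importFrom igraph graph_from_data_frame simplify V degree components
#'   induced_subgraph eigen_centrality distances neighbors ego vcount ecount
NULL

NETWORK_LAYERS <- c("chia_pet", "coexpression", "cotranslation", "ppi")

#' Construct a multi-omics network from an edge table
#'
#' Builds the union view of a layered interaction network: a simple undirected
#' graph with one edge per unordered gene pair, regardless of how many layers
#' (chromatin interaction, co-expression, co-translation, protein-protein
#' interaction) support that pair. Layer labels are retained for provenance.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and optionally
#'   `layer` (defaults to `"ppi"` when absent). Self-loops are dropped and
#'   duplicate unordered pairs within a layer are deduplicated.
#' @param extra_nodes character vector of gene IDs to include as (possibly
#'   isolated) nodes even if they appear in no edge.
#' @return An object of class `qtg_network`: a list with elements `graph`
#'   (the igraph union view), `edges` (the deduplicated layered edge table)
#'   and `nodes` (sorted gene IDs).
#' @export
network_from_edges <- function(edges, extra_nodes = character()) {
  stopifnot(is.data.frame(edges))
  if (!all(c("gene_a", "gene_b") %in% names(edges)))
    stop("edge table must have columns 'gene_a' and 'gene_b'")
  if (!"layer" %in% names(edges)) edges$layer <- "ppi"
  edges$gene_a <- as.character(edges$gene_a)
  edges$gene_b <- as.character(edges$gene_b)
  edges$layer <- as.character(edges$layer)
  bad <- setdiff(unique(edges$layer), NETWORK_LAYERS)
  if (length(bad) > 0)
    stop("unknown network layer(s): ", paste(bad, collapse = ", "))

  n_self <- sum(edges$gene_a == edges$gene_b)
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]

  # canonical unordered pair, then dedup within layer
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges$gene_a <- a
  edges$gene_b <- b
  key <- paste(a, b, edges$layer, sep = "\r")
  n_dup <- sum(duplicated(key))
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (n_self + n_dup > 0)
    message(sprintf("network_from_edges: dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_self, n_dup))

  nodes <- sort(unique(c(edges$gene_a, edges$gene_b, as.character(extra_nodes))))
  if (length(nodes) == 0) stop("network has no nodes")
  pair_key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  union_edges <- edges[!duplicated(pair_key), c("gene_a", "gene_b"), drop = FALSE]
  g <- igraph::graph_from_data_frame(union_edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g,
                 edges = edges[, c("gene_a", "gene_b", "layer")],
                 nodes = nodes),
            class = "qtg_network")
}

#' @exportS3Method base::print
print.qtg_network <- function(x, ...) {
  cat(sprintf("qtg_network: %d nodes, %d union edges, %d layered edges\n",
              length(x$nodes), igraph::ecount(x$graph), nrow(x$edges)))
  tab <- table(x$edges$layer)
  for (ly in names(tab)) cat(sprintf("  %-14s %d\n", ly, tab[[ly]]))
  invisible(x)
}

#' Load a multi-omics network edge list from a TSV file
#'
#' Reads a tab-separated edge list with columns `gene_a`, `gene_b` and an
#' optional third `layer` column (one of `chia_pet`, `coexpression`,
#' `cotranslation`, `ppi`; rows with no layer default to `ppi`).
#' `#`-prefixed comment lines are skipped. Self-loops and duplicate edges
#' within a layer are dropped with a message.
#'
#' @param edge_file path to the TSV edge list.
#' @param layer_filter optional character vector of layers to keep.
#' @return A [network_from_edges()] `qtg_network` object.
#' @export
load_network <- function(edge_file, layer_filter = NULL) {
  if (!file.exists(edge_file)) stop("edge file not found: ", edge_file)
  lines <- readLines(edge_file)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("empty edge file: ", edge_file)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    bad <- idx[which(nf < 2)[1]]
    stop(sprintf("malformed edge line %d in %s: need at least 2 tab-separated fields",
                 bad, edge_file))
  }
  # drop an optional header row
  first <- parts[[1]]
  if (identical(tolower(first[1]), "gene_a")) {
    parts <- parts[-1]
    idx <- idx[-1]
    if (length(parts) == 0) stop("empty edge file: ", edge_file)
  }
  edges <- data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    layer = vapply(parts, function(p) if (length(p) >= 3 && nzchar(p[3])) p[3] else "ppi",
                   character(1)),
    stringsAsFactors = FALSE)
  if (any(edges$gene_a == "" | edges$gene_b == "")) {
    bad <- idx[which(edges$gene_a == "" | edges$gene_b == "")[1]]
    stop(sprintf("malformed edge line %d in %s: empty gene ID", bad, edge_file))
  }
  if (!is.null(layer_filter)) {
    layer_filter <- match.arg(layer_filter, NETWORK_LAYERS, several.ok = TRUE)
    edges <- edges[edges$layer %in% layer_filter, , drop = FALSE]
    if (nrow(edges) == 0) stop("no edges remain after layer filter")
  }
  network_from_edges(edges)
}

#' Write a network edge list to TSV
#'
#' @param net a `qtg_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "qtg_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Node topology attributes of the union network
#'
#' Computes, per node: eccentricity (hops, within the node's connected
#' component), closeness (normalized within the component, in \[0,1\]),
#' degree, and eigenvector centrality (max-normalized per component).
#' Isolated nodes get all-zero attributes rather than being dropped, so the
#' gene universe is stable.
#'
#' @param net a `qtg_network`.
#' @return data.frame with columns `gene`, `eccentricity`, `closeness`,
#'   `degree`, `eigencentrality`, one row per node, in node order.
#' @export
node_topology <- function(net) {
  stopifnot(inherits(net, "qtg_network"))
  g <- net$graph
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  ecc <- numeric(n)
  clo <- numeric(n)
  eig <- numeric(n)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) == 1) next  # isolated node: all zero
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::distances(sub)
    ecc[members] <- apply(d, 1, max)
    clo[members] <- (length(members) - 1) / rowSums(d)
    ev <- igraph::eigen_centrality(sub, options = list(tol = 1e-10))$vector
    eig[members] <- ev
  }
  data.frame(gene = net$nodes, eccentricity = as.numeric(ecc),
             closeness = clo, degree = as.numeric(deg),
             eigencentrality = eig, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' First- and second-layer network neighbors of a gene
#'
#' Returns the genes at unweighted hop distance exactly 1 and exactly 2 from
#' the query gene on the union view. The two sets are disjoint and exclude
#' the query itself.
#'
#' @param net a `qtg_network`.
#' @param gene a gene ID present in the network.
#' @return list with character vectors `d1` and `d2`.
#' @export
layered_neighbors <- function(net, gene) {
  stopifnot(inherits(net, "qtg_network"))
  if (!gene %in% net$nodes) stop("gene not in network: ", gene)
  d <- as.vector(igraph::distances(net$graph, v = gene))
  list(d1 = sort(net$nodes[d == 1]), d2 = sort(net$nodes[d == 2]))
}

#' Shortest distances from every node to an ordered target set
#'
#' Hop distances on the union view from every network node to each target, in
#' target order. Distances beyond `cap`, unreachable pairs, and targets absent
#' from the network all map to the sentinel `cap + 1`, so downstream feature
#' matrices stay finite. Distance of a node to itself is 0.
#'
#' @param net a `qtg_network`.
#' @param targets ordered character vector of target gene IDs (non-empty).
#' @param cap positive integer distance cap (default 6).
#' @return numeric matrix, nodes x targets, with `net$nodes` rownames and
#'   `targets` colnames.
#' @export
distances_to_set <- function(net, targets, cap = 6L) {
  stopifnot(inherits(net, "qtg_network"))
  if (length(targets) == 0) stop("target list is empty")
  if (cap < 1) stop("cap must be >= 1")
  targets <- as.character(targets)
  present <- targets[targets %in% net$nodes]
  out <- matrix(cap + 1, nrow = length(net$nodes), ncol = length(targets),
                dimnames = list(net$nodes, targets))
  if (length(present) > 0) {
    d <- igraph::distances(net$graph, to = unique(present))
    d[!is.finite(d)] <- cap + 1
    d[d > cap + 1] <- cap + 1
    tp <- targets %in% net$nodes
    out[, tp] <- d[net$nodes, targets[tp], drop = FALSE]
  }
  out
}

#' Read a precomputed shortest-distance score table
#'
#' Reader for precomputed gene-level SD score tables distributed as (optionally
#' gzipped) TSV, e.g. a GEO supplementary file, with gene IDs in the first
#' column and the SD score in the last numeric column. This bypasses distance
#' computation entirely for users with a published score table.
#'
#' @param path path to a TSV or gzipped TSV.
#' @return named numeric vector of SD scores keyed by gene ID.
#' @export
read_sd_table <- function(path) {
  if (!file.exists(path)) stop("SD table not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  tab <- utils::read.delim(con, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("SD table needs at least two columns (gene, score)")
  num_cols <- which(vapply(tab, is.numeric, logical(1)))
  if (length(num_cols) == 0) stop("SD table has no numeric score column")
  scores <- tab[[max(num_cols)]]
  names(scores) <- as.character(tab[[1]])
  scores
}
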