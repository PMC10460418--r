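test_that("load_network dedups, drops self-loops and collapses layers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tppi", "B\tA\tppi", "A\tA\tppi"), f)
  net <- suppressMessages(load_network(f))
  expect_setequal(net$nodes, c("A", "B"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(igraph::ecount(net$graph), 1)

  writeLines(c("# comment", "A\tB\tchia_pet", "A\tB\tppi"), f)
  net <- suppressMessages(load_network(f))
  expect_equal(nrow(net$edges), 2)          # one per layer
  expect_equal(igraph::ecount(net$graph), 1) # union collapses to one edge

  # missing layer column defaults to ppi; filter keeps only requested layers
  writeLines(c("A\tB", "B\tC\tcoexpression"), f)
  net <- suppressMessages(load_network(f, layer_filter = "ppi"))
  expect_equal(net$edges$layer, "ppi")
  expect_setequal(net$nodes, c("A", "B"))
})

test_that("load_network rejects malformed and empty files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\tppi", "oops"), f)
  expect_error(load_network(f), "line 2")
  writeLines("# only a comment", f)
  expect_error(load_network(f), "empty")
  writeLines(c("A\tB\tnot_a_layer"), f)
  expect_error(load_network(f), "not_a_layer")
})

test_that("a random edge list round-trips through write/load unchanged", {
  set.seed(401)
  edges <- random_edges(60, 0.25)
  edges$layer <- sample(c("ppi", "coexpression", "chia_pet", "cotranslation"),
                        nrow(edges), replace = TRUE)
  expect_gt(nrow(edges), 400)
  net <- make_net(edges)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  net2 <- suppressMessages(load_network(f))
  expect_equal(net2$edges, net$edges)
  expect_identical(net2$nodes, net$nodes)
})

test_that("node topology matches hand values on path and star graphs", {
  path <- make_net(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
  topo <- node_topology(path)
  rownames(topo) <- topo$gene
  expect_equal(topo["B", "degree"], 2)
  expect_equal(topo["B", "eccentricity"], 1)
  expect_equal(topo["A", "eccentricity"], 2)
  expect_equal(topo["A", "closeness"], 2 / 3)

  star <- make_net(data.frame(gene_a = "C", gene_b = paste0("L", 1:4)))
  topo <- node_topology(star)
  expect_equal(topo$eigencentrality[topo$gene == "C"], 1)
  leaves <- topo$eigencentrality[topo$gene != "C"]
  expect_equal(length(unique(round(leaves, 10))), 1)
})

test_that("isolated nodes keep all-zero topology instead of being dropped", {
  net <- make_net(data.frame(gene_a = "A", gene_b = "B"),
                  extra_nodes = "LONER")
  topo <- node_topology(net)
  iso <- topo[topo$gene == "LONER", ]
  expect_equal(unlist(iso[, -1], use.names = FALSE), rep(0, 4))
})

test_that("topology of a random graph equals brute-force recomputation", {
  set.seed(402)
  edges <- random_edges(30, 0.12)
  net <- make_net(edges, extra_nodes = sprintf("N%03d", 1:30))
  topo <- node_topology(net)
  rownames(topo) <- topo$gene
  adj <- adj_list(edges, sprintf("N%03d", 1:30))
  ev <- eigen_oracle(edges, sprintf("N%03d", 1:30))
  for (v in names(adj)) {
    d <- bfs_dist(adj, v)
    reach <- d[is.finite(d)]
    expect_equal(topo[v, "degree"], length(adj[[v]]))
    if (length(reach) > 1) {
      expect_equal(topo[v, "eccentricity"], max(reach))
      expect_equal(topo[v, "closeness"], (length(reach) - 1) / sum(reach))
    } else {
      expect_equal(unlist(topo[v, -1], use.names = FALSE), rep(0, 4))
    }
    expect_equal(topo[v, "eigencentrality"], unname(ev[v]), tolerance = 1e-6)
  }
})

test_that("layered_neighbors returns disjoint distance-1 and distance-2 shells", {
  path <- make_net(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
  expect_equal(layered_neighbors(path, "A"), list(d1 = "B", d2 = "C"))
  tri <- make_net(data.frame(gene_a = c("A", "B", "A"),
                             gene_b = c("B", "C", "C")))
  got <- layered_neighbors(tri, "A")
  expect_setequal(got$d1, c("B", "C"))
  expect_length(got$d2, 0)
  expect_error(layered_neighbors(tri, "ZZZ"), "ZZZ")
})

test_that("layered_neighbors agrees with a BFS-by-levels oracle everywhere", {
  set.seed(403)
  edges <- random_edges(50, 0.06)
  nodes <- sprintf("N%03d", 1:50)
  net <- make_net(edges, extra_nodes = nodes)
  adj <- adj_list(edges, nodes)
  for (v in nodes) {
    d <- bfs_dist(adj, v)
    got <- layered_neighbors(net, v)
    expect_setequal(got$d1, names(d)[d == 1])
    expect_setequal(got$d2, names(d)[d == 2])
    expect_length(intersect(got$d1, got$d2), 0)
  }
})

test_that("distances_to_set: order, self-distance, sentinel and cap semantics", {
  path <- make_net(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
  d <- distances_to_set(path, "C", cap = 10)
  expect_equal(d[c("A", "B", "C"), "C"], c(A = 2, B = 1, C = 0))

  two_comp <- make_net(data.frame(gene_a = "A", gene_b = "A2"),
                       extra_nodes = "B")
  d <- distances_to_set(two_comp, "B", cap = 6)
  expect_equal(unname(d["A", "B"]), 7)   # unreachable -> cap + 1
  expect_equal(unname(d["B", "B"]), 0)

  # absent target column is all sentinel; long chains clamp at cap + 1
  chain <- make_net(data.frame(gene_a = paste0("C", 1:9),
                               gene_b = paste0("C", 2:10)))
  d <- distances_to_set(chain, c("C1", "GHOST"), cap = 3)
  expect_true(all(d[, "GHOST"] == 4))
  expect_equal(unname(d["C10", "C1"]), 4)
  expect_equal(unname(d["C4", "C1"]), 3)

  expect_error(distances_to_set(path, character()), "empty")
  expect_error(distances_to_set(path, "C", cap = 0), "cap")
})

test_that("distances to a target panel match per-target BFS", {
  set.seed(404)
  edges <- random_edges(40, 0.07)
  nodes <- sprintf("N%03d", 1:40)
  net <- make_net(edges, extra_nodes = nodes)
  targets <- sample(nodes, 8)
  d <- distances_to_set(net, targets, cap = 50)
  adj <- adj_list(edges, nodes)
  for (t in targets) {
    ref <- bfs_dist(adj, t)
    ref[!is.finite(ref)] <- 51
    expect_equal(d[, t], ref[rownames(d)])
  }
})

test_that("distance metric axioms hold on random graphs", {
  set.seed(405)
  for (rep in 1:5) {
    edges <- random_edges(25, 0.1)
    net <- make_net(edges, extra_nodes = sprintf("N%03d", 1:25))
    d <- distances_to_set(net, net$nodes, cap = 100)
    expect_equal(d, t(d))                     # symmetry
    trips <- replicate(40, sample(net$nodes, 3), simplify = FALSE)
    for (tr in trips)                          # triangle inequality
      expect_lte(d[tr[1], tr[3]], d[tr[1], tr[2]] + d[tr[2], tr[3]])
    # shell sizes agree with the all-pairs matrix
    v <- sample(net$nodes, 1)
    shells <- layered_neighbors(net, v)
    expect_length(shells$d1, sum(d[v, ] == 1))
    expect_length(shells$d2, sum(d[v, ] == 2))
  }
})

test_that("adding an edge never increases any pairwise distance", {
  set.seed(406)
  edges <- random_edges(20, 0.08)
  nodes <- sprintf("N%03d", 1:20)
  net <- make_net(edges, extra_nodes = nodes)
  before <- distances_to_set(net, nodes, cap = 100)
  for (rep in 1:10) {
    new_pair <- sample(nodes, 2)
    edges2 <- rbind(edges, data.frame(gene_a = new_pair[1],
                                      gene_b = new_pair[2]))
    after <- distances_to_set(make_net(edges2, extra_nodes = nodes),
                              nodes, cap = 100)
    expect_true(all(after <= before))
    edges <- edges2
    before <- after
  }
})

test_that("precomputed SD score tables are read as named vectors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsd", "G1\t3.02", "G2\t0"), f)
  s <- read_sd_table(f)
  expect_equal(s, c(G1 = 3.02, G2 = 0))
  # gzipped variant reads identically
  fgz <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(fgz, "w"); writeLines(c("gene\tsd", "G1\t3.02", "G2\t0"), con)
  close(con)
  expect_equal(read_sd_table(fgz), s)
})
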