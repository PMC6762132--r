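test_that("toy graph construction matches component descriptors", {
  g <- make_toy_graph(toy_graph_spec(list(list(kind = "path", size = 5))))
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 5)
  expect_equal(sum(igraph::degree(g) == 1), 2)

  g <- make_toy_graph(toy_graph_spec(list(list(kind = "cycle", size = 4))))
  expect_equal(igraph::vcount(g), 4)
  expect_true(all(igraph::degree(g) == 2))
  expect_equal(cycle_rank(g), 1)

  g <- make_toy_graph(toy_graph_spec(list(
    list(kind = "path", size = 3), list(kind = "cycle", size = 4),
    list(kind = "isolated-edge", size = 1))))
  expect_equal(igraph::components(g)$no, 3)
  expect_equal(igraph::ecount(g), 8)

  expect_error(toy_graph_spec(list(list(kind = "blob", size = 2))),
               "unknown component kind")
  expect_error(toy_graph_spec(list(list(kind = "isolated-edge", size = 3))))
})

test_that("mean degree counts all nodes, self-loops twice", {
  path3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(mean_degree(path3), 4 / 3)
  expect_equal(mean_degree(igraph::make_ring(3)), 2)
  loop <- igraph::make_graph(c(1, 1), directed = FALSE)
  expect_equal(mean_degree(loop), 2)
  expect_error(mean_degree(igraph::make_empty_graph(0, directed = FALSE)),
               "no nodes")
})

test_that("giant cluster picks the edge-richest component", {
  g <- igraph::disjoint_union(igraph::make_ring(4, circular = FALSE),
                              igraph::make_ring(8, circular = FALSE))
  gc <- giant_cluster(g)
  expect_equal(unname(gc["giant_size"]), 7)
  expect_equal(unname(gc["giant_frac"]), 0.7)
  expect_equal(unname(giant_cluster(igraph::make_ring(5))["giant_frac"]), 1)
  expect_error(giant_cluster(igraph::make_empty_graph(3, directed = FALSE)),
               "no edges")
})

test_that("loop sizes equal the minimum-weight cycle basis", {
  expect_equal(loop_sizes(igraph::make_ring(4)), 4)
  expect_equal(loop_sizes(igraph::make_ring(9, circular = FALSE)),
               numeric(0))

  # theta graph: two degree-3 junctions joined by chains of 2, 2, 2 edges;
  # expectation computed by exhaustive cycle enumeration
  theta <- igraph::make_graph(c(1, 3, 3, 2, 1, 4, 4, 2, 1, 5, 5, 2),
                              directed = FALSE)
  expect_equal(loop_sizes(theta), enumerate_min_basis(theta))
  expect_equal(loop_sizes(theta), c(4, 4))

  lolli <- make_lollipop(4, 3)
  expect_equal(loop_sizes(lolli), 4)
  expect_equal(branch_lengths(lolli), 3)

  # multigraph cases: parallel edges and self-loops are genuine cycles
  dumbbell <- igraph::make_graph(c(1, 2, 1, 2, 2, 2), directed = FALSE)
  expect_equal(loop_sizes(dumbbell), enumerate_min_basis(dumbbell))
})

test_that("nested cycles resolve to the minimal basis", {
  # two squares sharing an edge: basis is [4, 4], not the outer 6-cycle
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 4, 4, 1, 2, 5, 5, 6, 6, 3),
                          directed = FALSE)
  expect_equal(loop_sizes(g), enumerate_min_basis(g))
  expect_equal(loop_sizes(g), c(4, 4))
})

test_that("branch lengths require an open end", {
  expect_equal(branch_lengths(igraph::make_ring(6, circular = FALSE)), 5)
  star <- igraph::make_graph(c(1, 2, 2, 3, 1, 4, 4, 5, 1, 6, 6, 7),
                             directed = FALSE)  # 3 arms of 2 edges
  expect_equal(branch_lengths(star), c(2, 2, 2))
  expect_equal(branch_lengths(igraph::make_ring(6)), numeric(0))
})

test_that("cluster size distribution is a cumulative probability", {
  g <- igraph::disjoint_union(igraph::make_ring(3, circular = FALSE),
                              igraph::make_ring(3, circular = FALSE),
                              igraph::make_ring(7, circular = FALSE))
  d <- cluster_size_distribution(g)
  expect_equal(sort(d$sizes), c(2, 2, 6))
  expect_equal(d$cumulative$cum_prob[d$cumulative$size == 2], 2 / 3)
  expect_equal(d$cumulative$cum_prob[d$cumulative$size == 6], 1)
  expect_equal(sum(d$sizes), igraph::ecount(g))
})

test_that("network_stats bundles the metrics consistently", {
  g <- make_toy_graph(toy_graph_spec(list(
    list(kind = "path", size = 3), list(kind = "cycle", size = 4),
    list(kind = "isolated-edge", size = 1))))
  st <- network_stats(g)
  expect_equal(st$n_edges, 8)
  expect_equal(st$n_clusters, 3)
  expect_equal(st$avg_cluster_size, 8 / 3)
  expect_equal(st$giant_size, 4)
  expect_equal(st$giant_frac, 0.5)
  expect_equal(st$giant_size, max(st$cluster_sizes))
  expect_equal(sum(st$cluster_sizes), st$n_edges)
})

test_that("loop count equals cycle rank on random toys and simulations", {
  for (seed in 1:6) {
    g <- make_toy_graph(random_toy_spec(seed))
    expect_equal(length(loop_sizes(g)), cycle_rank(g))
    expect_equal(sum(cluster_sizes(g)), igraph::ecount(g))
  }
  for (seed in 11:16) {
    r <- ff_run(80, ff_rates(2e-2, 5e-3), seed = seed)
    expect_equal(length(loop_sizes(r$graph)), cycle_rank(r$graph))
    expect_equal(sum(cluster_sizes(r$graph)), 80)
    expect_equal(network_stats(r$graph)$giant_size,
                 max(cluster_sizes(r$graph)))
  }
})

test_that("statistics agree between provenances for equal topology", {
  g1 <- make_toy_graph(toy_graph_spec(list(list(kind = "theta", size = 7),
                                           list(kind = "path", size = 4))))
  g2 <- as_mito_graph(igraph::graph_from_edgelist(
    igraph::as_edgelist(g1), directed = FALSE), provenance = "simulated")
  s1 <- network_stats(g1); s2 <- network_stats(g2)
  for (f in c("n_edges", "mean_degree", "n_clusters", "giant_frac")) {
    expect_equal(s1[[f]], s2[[f]])
  }
  expect_equal(s1$loop_sizes, s2$loop_sizes)
  expect_equal(s1$branch_lengths, s2$branch_lengths)
})

test_that("skeleton pixels become nodes with pruned diagonal adjacency", {
  m <- matrix(FALSE, 5, 5)
  m[3, 2:4] <- TRUE                      # straight 3-pixel line
  g <- skeleton_to_graph(m)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::degree(g)), c(1, 1, 2))

  m <- matrix(FALSE, 5, 5)
  m[3, 2:4] <- TRUE; m[2, 3] <- TRUE     # T-junction of 4 pixels
  g <- skeleton_to_graph(m)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::degree(g)), c(1, 1, 1, 3))

  m <- matrix(FALSE, 6, 6)               # 1-px rectangular ring
  m[2, 2:5] <- TRUE; m[5, 2:5] <- TRUE; m[2:5, 2] <- TRUE; m[2:5, 5] <- TRUE
  g <- skeleton_to_graph(m)
  p <- sum(m)
  expect_equal(igraph::vcount(g), p)
  expect_equal(igraph::ecount(g), p)
  expect_true(all(igraph::degree(g) == 2))
  expect_equal(cycle_rank(g), 1)
})

test_that("graphml round-trips a multigraph", {
  g <- make_lollipop(5, 2)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_mito_graph(g, f)
  g2 <- read_mito_graph(f)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::degree(g2)), sort(igraph::degree(g)))
  expect_equal(loop_sizes(g2), loop_sizes(g))
})
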