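test_that("density, clustering and APL match brute-force oracles on all small graphs", {
  for (n in 2:4) {
    n_pairs <- n * (n - 1) / 2
    for (mask in 0:(2^n_pairs - 1)) {
      A <- mask_to_adj(n, mask)
      g <- adj_to_graph(A)
      expect_equal(net_density(g), oracle_density(A))
      expect_equal(clustering_global(g), oracle_clustering(A))
      if (sum(A) > 0) {
        expect_equal(net_apl(g), oracle_apl(A))
      } else {
        expect_error(net_apl(g), "edgeless")
      }
    }
  }
  # full enumeration of the 1024 five-node graphs
  for (mask in 0:1023) {
    A <- mask_to_adj(5, mask)
    g <- adj_to_graph(A)
    expect_equal(net_density(g), oracle_density(A))
    expect_equal(clustering_global(g), oracle_clustering(A))
    if (sum(A) > 0) expect_equal(net_apl(g), oracle_apl(A))
  }
})

test_that("network construction keeps positive similarities only", {
  J <- complete_weight_matrix(4, 0.5)
  g <- build_network(J, bin = "b")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 6)
  expect_equal(igraph::graph_attr(g, "bin"), "b")
  expect_equal(sort(unique(igraph::E(g)$weight)), 0.5)

  J0 <- matrix(0, 3, 3); diag(J0) <- 1
  dimnames(J0) <- list(letters[1:3], letters[1:3])
  expect_equal(igraph::ecount(build_network(J0)), 0)

  J2 <- complete_weight_matrix(3, 0.4)
  J2["C1", "C2"] <- J2["C2", "C1"] <- 0
  expect_equal(igraph::ecount(build_network(J2)), 2)
})

test_that("worked metric examples: complete, path, sparse", {
  k4 <- build_network(complete_weight_matrix(4, 0.3))
  expect_equal(net_density(k4), 1)
  expect_equal(clustering_global(k4), 1)
  expect_equal(net_apl(k4), 1)

  path3 <- adj_to_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(clustering_global(path3), 0)
  expect_equal(net_apl(path3), 4 / 3)

  # 8 nodes, 3 edges
  A <- matrix(0, 8, 8)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- A[5, 6] <- A[6, 5] <- 1
  expect_equal(net_density(adj_to_graph(A)), 3 / 28)

  # two disjoint edges: within-component average only
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(net_apl(adj_to_graph(A2)), 1)
})

test_that("betweenness and eigenvector follow the standard conventions", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:5)
  b <- node_betweenness(star)
  expect_equal(unname(b["v1"]), 6)
  expect_equal(unname(b[paste0("v", 2:5)]), rep(0, 4))
  e <- node_eigenvector(star)
  expect_equal(unname(e["v1"]), 1)
  expect_true(all(e[paste0("v", 2:5)] < 1))
  k4 <- build_network(complete_weight_matrix(4))
  expect_equal(unname(node_betweenness(k4)), rep(0, 4))
})

test_that("Leiden/CPM finds the exhaustive-search optimum on small graphs", {
  # two disconnected 3-cliques
  g <- igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                          directed = FALSE)
  igraph::V(g)$name <- letters[1:6]
  part <- leiden_cpm(g, resolution = 0.02, iterations = 10, restarts = 20,
                     seed = 1)
  best <- oracle_best_cpm(g, 0.02)
  expect_equal(part$n_communities, 2)
  expect_equal(part$quality, best$quality, tolerance = 1e-12)
  expect_equal(unname(part$membership[1:3]), rep(part$membership[[1]], 3))
  expect_false(part$membership[[1]] == part$membership[[4]])

  # complete uniform-weight graph at low resolution: one community
  k5 <- build_network(complete_weight_matrix(5, 0.8))
  p5 <- leiden_cpm(k5, resolution = 0.02, iterations = 10, restarts = 10,
                   seed = 2)
  expect_equal(p5$n_communities, 1)
  expect_equal(p5$quality, oracle_best_cpm(k5, 0.02)$quality,
               tolerance = 1e-12)
  expect_true(p5$quality_norm >= 0 && p5$quality_norm <= 1)

  # random weighted graphs against the partition-enumeration oracle
  set.seed(5)
  for (i in 1:5) {
    A <- mask_to_adj(5, sample(1:1023, 1))
    g5 <- adj_to_graph(A)
    igraph::E(g5)$weight <- runif(igraph::ecount(g5), 0.1, 1)
    p <- leiden_cpm(g5, resolution = 0.1, iterations = 10, restarts = 30,
                    seed = i)
    expect_equal(p$quality, oracle_best_cpm(g5, 0.1)$quality,
                 tolerance = 1e-9)
  }

  # singleton graph
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "only"
  expect_equal(leiden_cpm(g1)$n_communities, 1)
})

test_that("Leiden quality beats the trivial partitions", {
  set.seed(9)
  B <- matrix(rbinom(6 * 10, 1, 0.4), nrow = 6)
  B[rowSums(B) == 0, 1] <- 1L
  rownames(B) <- paste0("c", 1:6)
  g <- build_network(jaccard_matrix(B))
  part <- leiden_cpm(g, resolution = 0.05, iterations = 10, restarts = 10,
                     seed = 3)
  singleton <- cpm_quality(g, seq_len(igraph::vcount(g)), 0.05)
  allinone <- cpm_quality(g, rep(1L, igraph::vcount(g)), 0.05)
  expect_gte(part$quality, singleton)
  expect_gte(part$quality, allinone)
})

test_that("Leiden recovers planted partitions across seeds", {
  # 3 planted blocks of 4 nodes: strong within (0.9), weak between (0.05)
  truth <- rep(1:3, each = 4)
  J <- matrix(0.05, 12, 12)
  for (b in 1:3) J[truth == b, truth == b] <- 0.9
  diag(J) <- 1
  dimnames(J) <- list(paste0("n", 1:12), paste0("n", 1:12))
  g <- build_network(J)
  aris <- vapply(1:20, function(s) {
    p <- leiden_cpm(g, resolution = 0.3, iterations = 10, restarts = 10,
                    seed = s)
    mclust::adjustedRandIndex(p$membership, truth)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("node turnover ratio: worked example, zero, sign, antisymmetry", {
  n1 <- c("A", "B", "C", "D")
  n2 <- c("A", "B", "E", "F", "G", "H", "I")  # keeps 2, adds 5
  t1 <- ntr(list(b1 = n1, b2 = n2))
  expect_equal(t1$created, 5)
  expect_equal(t1$destroyed, 2)
  expect_equal(round(t1$ntr, 2), 0.43)

  expect_equal(ntr(list(a = n1, b = n1))$ntr, 0)

  shrink <- ntr(list(a = n1, b = c("A", "B")))
  expect_lt(shrink$ntr, 0)

  # antisymmetry: swapping created/destroyed at fixed |N_t| flips the sign
  fwd <- ntr(list(a = c("A", "B", "C"), b = c("A", "D", "E")))
  bwd <- ntr(list(a = c("A", "D", "E"), b = c("A", "B", "C")))
  expect_equal(fwd$ntr, -bwd$ntr)

  expect_error(ntr(list(a = n1)), "at least 2 bins")
  expect_error(ntr(list(a = n1, b = character(0))), "empty node set")
})
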