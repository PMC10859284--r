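test_that("closed-form identities on canonical graphs", {
  ## complete graph K6
  k6 <- matrix(1, 6, 6); diag(k6) <- 0
  expect_equal(node_degree(k6), rep(5L, 6))
  expect_equal(node_clustering(k6), rep(1, 6))
  expect_equal(char_path_length(k6)$LP, 1)
  expect_equal(global_efficiency(k6), 1)
  expect_equal(node_betweenness(k6), rep(0, 6))

  ## star with 5 nodes: center degree 4, BC = C(4,2) = 6
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(node_degree(star), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(node_betweenness(star), c(6, 0, 0, 0, 0))

  ## path of 4 nodes: LP = (1+1+1+2+2+3)/6
  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  expect_equal(char_path_length(p4)$LP, 10 / 6)

  ## path of 3: middle clustering 0, BC 1; E_glob = mean(1, 1, 1/2)
  p3 <- matrix(0, 3, 3); p3[cbind(1:2, 2:3)] <- 1; p3 <- p3 + t(p3)
  expect_equal(node_clustering(p3)[2], 0)
  expect_equal(node_betweenness(p3), c(0, 1, 0))
  expect_equal(global_efficiency(p3), 5 / 6)

  ## triangle: clustering 1 everywhere
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(node_clustering(k3), rep(1, 3))

  ## 4-cycle: two shortest paths between opposite corners -> BC 1/2 each
  c4 <- matrix(0, 4, 4); c4[cbind(1:4, c(2, 3, 4, 1))] <- 1; c4 <- c4 + t(c4)
  expect_equal(node_betweenness(c4), rep(0.5, 4))

  ## empty graph
  e5 <- matrix(0, 5, 5)
  expect_equal(node_degree(e5), rep(0L, 5))
  expect_true(is.na(char_path_length(e5)$LP))
  expect_equal(global_efficiency(e5), 0)
})

test_that("disconnected graphs use the reachable-pair convention", {
  ## two disjoint K2 components: LP = 1 over reachable, 4/6 pairs unreachable
  a <- matrix(0, 4, 4); a[1, 2] <- a[3, 4] <- 1; a <- a + t(a)
  pl <- char_path_length(a)
  expect_equal(pl$LP, 1)
  expect_equal(pl$unreachable_frac, 8 / 12) # ordered pairs
  expect_equal(global_efficiency(a), (4 * 1) / 12)
})

test_that("metrics match brute-force oracles on seeded random graphs", {
  for (seed in 1:30) {
    n <- sample(4:12, 1)
    a <- random_adjacency(n, runif(1, 0.2, 0.7), seed = 1000 + seed)
    expect_equal(node_degree(a), as.integer(rowSums(a)))
    expect_equal(node_clustering(a), oracle_clustering(a), tolerance = 1e-12)
    expect_equal(node_betweenness(a), oracle_betweenness(a), tolerance = 1e-12)
    expect_equal(distance_matrix(a), oracle_distances(a))
    lp <- char_path_length(a)$LP
    olp <- oracle_lp(a)
    if (is.na(olp)) expect_true(is.na(lp)) else
      expect_equal(lp, olp, tolerance = 1e-12)
    expect_equal(global_efficiency(a), oracle_eglob(a), tolerance = 1e-12)
  }
})

test_that("metrics match igraph as an independent reference", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    a <- random_adjacency(10, 0.35, seed = 2000 + seed)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(node_degree(a), unname(igraph::degree(g)))
    expect_equal(node_betweenness(a), unname(igraph::betweenness(g)),
                 tolerance = 1e-12)
    tr <- suppressWarnings(igraph::transitivity(g, type = "localundirected",
                                                isolates = "zero"))
    expect_equal(node_clustering(a), unname(tr), tolerance = 1e-12)
  }
})

test_that("handshake and isomorphism invariance hold", {
  for (seed in 1:10) {
    a <- random_adjacency(9, 0.4, seed = 3000 + seed)
    expect_equal(sum(node_degree(a)), sum(a))
    perm <- sample(9)
    ap <- a[perm, perm]
    expect_equal(node_degree(ap), node_degree(a)[perm])
    expect_equal(node_betweenness(ap), node_betweenness(a)[perm],
                 tolerance = 1e-12)
    expect_equal(global_efficiency(ap), global_efficiency(a),
                 tolerance = 1e-12)
    ## BC bounds
    n <- 9
    expect_true(all(node_betweenness(a) >= 0))
    expect_true(all(node_betweenness(a) <= (n - 1) * (n - 2) / 2 + 1e-12))
  }
})

test_that("rewiring preserves degrees and simplicity", {
  for (seed in 1:5) {
    a <- random_adjacency(20, 0.2, seed = 4000 + seed)
    set.seed(seed)
    r <- rewire_preserving_degree(a)
    expect_equal(rowSums(r), rowSums(a))
    expect_equal(r, t(r))
    expect_true(all(diag(r) == 0))
    expect_true(all(r %in% c(0, 1)))
  }
})

test_that("small-worldness: complete graph gives exactly 1, lattice > 1, ER ~ 1", {
  k8 <- matrix(1, 8, 8); diag(k8) <- 0
  expect_equal(small_worldness(k8, n_null = 3, seed = 1)$SW, 1)

  ## ring lattice, each node linked to 4 nearest neighbors: high CP, long LP
  n <- 40
  lat <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in 1:2) {
    j <- ((i - 1 + k) %% n) + 1
    lat[i, j] <- lat[j, i] <- 1
  }
  expect_gt(small_worldness(lat, n_null = 10, seed = 7)$SW, 1)

  ## dense ER random graph is its own null
  er <- random_adjacency(60, 0.25, seed = 99)
  sw <- small_worldness(er, n_null = 10, seed = 3)$SW
  expect_lt(abs(sw - 1), 0.25)
})

test_that("graph_metrics bundles all measures consistently and is seeded", {
  a <- random_adjacency(15, 0.3, seed = 5)
  m1 <- graph_metrics(a, n_null = 5, seed = 42)
  m2 <- graph_metrics(a, n_null = 5, seed = 42)
  expect_equal(m1$SW, m2$SW)
  expect_equal(m1$mean_DC, mean(node_degree(a)))
  expect_equal(m1$mean_CP, mean(node_clustering(a)))
  expect_equal(m1$n_edges, sum(a) / 2)
})
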