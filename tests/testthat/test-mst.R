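test_that("MST keeps the strongest coherences: triangle analytic case", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9   # AB
  W[2, 3] <- W[3, 2] <- 0.8   # BC
  W[1, 3] <- W[3, 1] <- 0.5   # AC
  tr <- minimum_spanning_tree(W)
  expect_equal(tr$edges[order(tr$edges[, 1]), ],
               rbind(c(1L, 2L), c(2L, 3L)))
})

test_that("MST matches exhaustive enumeration on complete 4-node graphs", {
  set.seed(201)
  for (rep in 1:25) {
    W <- random_weighted_graph(4, density = 1)
    tr <- minimum_spanning_tree(W)
    got <- tr$edges[order(tr$edges[, 1], tr$edges[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle_mst_edges(W)))
  }
})

test_that("MST is deterministic under ties and equals igraph on distinct weights", {
  W <- matrix(0.5, 6, 6); diag(W) <- 0
  expect_warning(Wc <- generate_sw_matrix(n = 6, k = 2, weight_sd = 0,
                                          noise_sd = 0, noise_mean = 0.5,
                                          weight_mean = 0.5, seed = 1),
                 "tie")
  t1 <- minimum_spanning_tree(W)
  t2 <- minimum_spanning_tree(W)
  expect_identical(t1$edges, t2$edges)
  # independent route: igraph MST total distance agrees when weights distinct
  set.seed(202)
  for (rep in 1:10) {
    W <- random_weighted_graph(8)
    tr <- minimum_spanning_tree(W)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    igraph::E(g)$weight <- 1 / igraph::E(g)$weight
    ig <- igraph::mst(g)
    expect_equal(sum(1 / W[tr$edges]), sum(igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("MST edge set is invariant under strictly monotone distance transforms", {
  set.seed(203)
  for (rep in 1:10) {
    W <- random_weighted_graph(7)
    e1 <- minimum_spanning_tree(W)$edges
    e2 <- minimum_spanning_tree(W^3)$edges        # monotone in w
    e3 <- minimum_spanning_tree(0.5 * W)$edges
    expect_identical(e1, e2)
    expect_identical(e1, e3)
  }
})

test_that("tree betweenness: leaves 0, star centre (n-1)(n-2), path middle 2", {
  star <- spanning_tree(84, cbind(1L, 2:84))
  bc <- tree_betweenness(star)
  expect_equal(bc[1], 83 * 82)    # 6806
  expect_true(all(bc[-1] == 0))
  path3 <- spanning_tree(3, rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(tree_betweenness(path3), c(0, 2, 0))
})

test_that("tree metrics match oracles on random trees", {
  set.seed(204)
  for (rep in 1:15) {
    n <- sample(5:8, 1)
    tr <- random_tree(n)
    expect_equal(tree_betweenness(tr), oracle_tree_bc(tr))
    ecc <- eccentricity_and_diameter(tr)
    expect_equal(ecc$eccentricity, oracle_tree_ecc(tr))
    expect_equal(ecc$diameter, max(oracle_tree_ecc(tr)))
    expect_equal(leaf_fraction(tr),
                 sum(tabulate(c(tr$edges), n) == 1) / (n - 1))
  }
})

test_that("ordered-pair betweenness is twice the unordered igraph convention", {
  set.seed(205)
  for (rep in 1:10) {
    tr <- random_tree(sample(10:30, 1))
    g <- igraph::graph_from_edgelist(tr$edges, directed = FALSE)
    expect_equal(tree_betweenness(tr), 2 * igraph::betweenness(g))
  }
})

test_that("star and path extremes: leaf fraction versus diameter", {
  star <- spanning_tree(84, cbind(1L, 2:84))
  tm_star <- tree_metrics(star)
  expect_equal(tm_star$leaf_fraction, 1)
  expect_equal(tm_star$diameter, 2L)
  expect_equal(tm_star$eccentricity[1], 1L)
  expect_true(all(tm_star$eccentricity[-1] == 2L))
  expect_equal(tm_star$max_bc, 6806)

  path84 <- spanning_tree(84, cbind(1:83, 2:84))
  tm_path <- tree_metrics(path84)
  expect_equal(tm_path$leaf_fraction, 2 / 83)
  expect_equal(tm_path$diameter, 83L)

  path5 <- spanning_tree(5, cbind(1:4, 2:5))
  ecc5 <- eccentricity_and_diameter(path5)
  expect_equal(ecc5$eccentricity, c(4, 3, 2, 3, 4))
  expect_equal(ecc5$diameter, 4)
  expect_equal(ecc5$avg_eccentricity, 3.2)
  expect_equal(leaf_fraction(path5), 0.5)
})

test_that("handshake lemma and tree invariants hold on MSTs of random graphs", {
  set.seed(206)
  for (rep in 1:5) {
    W <- generate_sw_matrix(n = 84, seed = rep)
    tr <- minimum_spanning_tree(W)
    tm <- tree_metrics(tr)
    expect_equal(nrow(tr$edges), 83L)
    expect_equal(sum(tm$degree), 2L * 83L)
    expect_equal(tm$diameter, max(tm$eccentricity))
    expect_lte(tm$max_bc, 83 * 82)
    expect_gte(sum(tm$degree == 1L), 2L)
    expect_lte(tm$diameter, 83L)
  }
})

test_that("disconnected or malformed inputs are rejected", {
  Wd <- matrix(0, 4, 4)
  Wd[1, 2] <- Wd[2, 1] <- 1
  Wd[3, 4] <- Wd[4, 3] <- 1
  expect_error(minimum_spanning_tree(Wd), "disconnected")
  expect_error(spanning_tree(4, cbind(c(1L, 2L, 1L), c(2L, 3L, 3L))),
               "not a tree")
  expect_error(spanning_tree(4, cbind(1:2, 2:3)), "exactly 3 edges")
})
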