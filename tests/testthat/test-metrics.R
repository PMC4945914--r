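path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
star4 <- { a <- matrix(0, 4, 4); a[1, 2:4] <- 1; a + t(a) }
k3 <- matrix(1, 3, 3) - diag(3)
two_k3 <- rbind(cbind(k3, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), k3))

test_that("global efficiency closed forms", {
  expect_equal(global_efficiency(matrix(1, 5, 5) - diag(5)), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
})

test_that("betweenness closed forms", {
  nb <- node_betweenness(star4)
  expect_equal(nb$values, c(3, 0, 0, 0))
  expect_equal(node_betweenness(matrix(1, 5, 5) - diag(5))$values, rep(0, 5))
  eb <- edge_betweenness(path3)
  expect_equal(sort(eb$values$ebc), c(2, 2))      # each edge serves 2 pairs
  # bridge between two triangles carries all 9 cross pairs plus its own ends
  bridge <- two_k3; bridge[3, 4] <- bridge[4, 3] <- 1
  ebb <- edge_betweenness(bridge)$values
  expect_equal(ebb$ebc[ebb$i == 3 & ebb$j == 4], 9)
  single <- matrix(0, 2, 2); single[1, 2] <- single[2, 1] <- 1
  expect_equal(edge_betweenness(single)$values$ebc, 1)
})

test_that("local efficiency closed forms and the tree property", {
  expect_equal(local_efficiency(k3)$mean, 1)
  set.seed(1)
  for (k in 1:10) {
    W <- random_weights(sample(5:9, 1))
    expect_equal(local_efficiency(mst_binarize(W))$mean, 0)
  }
})

test_that("modularity closed forms", {
  expect_equal(modularity_q(two_k3, c(1, 1, 1, 2, 2, 2)), 0.5)
  set.seed(2)
  g <- random_adjacency(7, 0.4)
  if (sum(g) > 0) expect_equal(modularity_q(g, rep(1, 7)), 0)
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 2, 3)), "empty graph")
})

test_that("the modularity optimizer attains the exhaustive optimum (N <= 8)", {
  set.seed(3)
  graphs <- c(
    list(two_k3, star4),
    lapply(1:6, function(k) random_adjacency(sample(5:7, 1), runif(1, 0.3, 0.6)))
  )
  for (A in graphs) {
    if (sum(A) == 0) next
    opt <- modularity_optimal(A)
    expect_equal(opt$Q, oracle_best_partition_q(A), tolerance = 1e-12)
    expect_equal(modularity_q(A, opt$membership), opt$Q)
  }
})

test_that("assortativity closed forms and undefined cases", {
  expect_equal(assortativity_degree(star4), -1)
  ring5 <- matrix(0, 5, 5)
  for (i in 1:5) ring5[i, i %% 5 + 1] <- 1
  ring5 <- ring5 + t(ring5)
  r <- assortativity_degree(ring5)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "degree-regular")
})

test_that("all metrics agree with independent oracles on random graphs", {
  set.seed(4)
  for (k in 1:8) {
    A <- random_adjacency(sample(5:8, 1), runif(1, 0.3, 0.7))
    if (sum(A) < 4) next
    expect_equal(global_efficiency(A), oracle_global_efficiency(A))
    expect_equal(node_betweenness(A)$values, oracle_node_betweenness(A),
                 tolerance = 1e-10)
    eb <- edge_betweenness(A)
    oeb <- oracle_edge_betweenness(A)
    expect_equal(eb$values$ebc, oeb[cbind(eb$values$i, eb$values$j)],
                 tolerance = 1e-10)
    # cross-check against igraph as a second, packaged implementation
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(node_betweenness(A)$values, unname(igraph::betweenness(g)),
                 tolerance = 1e-10)
    r <- assortativity_degree(A)
    if (!is.na(r)) {
      expect_equal(r, igraph::assortativity_degree(g), tolerance = 1e-10)
    }
    # local efficiency against a literal subgraph re-implementation
    le_oracle <- mean(vapply(seq_len(nrow(A)), function(i) {
      nb <- which(A[i, ] > 0)
      if (length(nb) < 2) 0 else oracle_global_efficiency(A[nb, nb, drop = FALSE])
    }, numeric(1)))
    expect_equal(local_efficiency(A)$mean, le_oracle)
  }
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(5)
  for (k in 1:10) {
    A <- random_adjacency(7, 0.3)
    zero <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    B <- A
    B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(B), global_efficiency(A))
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(6)
  A <- random_adjacency(7, 0.5)
  p <- sample(7)
  B <- A[p, p]
  expect_equal(global_efficiency(A), global_efficiency(B))
  expect_equal(sort(node_betweenness(A)$values), sort(node_betweenness(B)$values),
               tolerance = 1e-10)
  expect_equal(local_efficiency(A)$mean, local_efficiency(B)$mean)
  expect_equal(modularity_optimal(A)$Q, modularity_optimal(B)$Q, tolerance = 1e-12)
  ra <- assortativity_degree(A); rb <- assortativity_degree(B)
  expect_equal(as.numeric(ra), as.numeric(rb), tolerance = 1e-12)
})

test_that("graph_metric dispatches all six metrics", {
  set.seed(7)
  A <- random_adjacency(8, 0.5)
  for (m in c("global_efficiency", "node_betweenness", "edge_betweenness",
              "local_efficiency", "modularity")) {
    expect_true(is.finite(graph_metric(A, m)), label = m)
  }
  expect_error(graph_metric(A, "smallworldness"), "'arg'")
})
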