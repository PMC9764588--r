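net_from <- function(w, roles = NULL) {
  labels <- rownames(w)
  if (is.null(roles)) {
    roles <- stats::setNames(rep("financial_agents", length(labels)), labels)
  }
  build_network(flow_matrix(w), roles)
}

path_graph <- function() {
  labels <- c("a", "b", "c")
  w <- named_matrix(rep(0, 9), labels)
  w["a", "b"] <- 1
  w["b", "c"] <- 1
  net_from(w)
}

test_that("degree counts links per direction and ignores weights", {
  labels <- c("a", "b", "c")
  w <- named_matrix(rep(0, 9), labels)
  w["a", "b"] <- 42
  g <- net_from(w)
  expect_equal(degree_centrality(g, "out")[["a"]], 1)
  expect_equal(degree_centrality(g, "in")[["b"]], 1)
  expect_equal(degree_centrality(g, "total")[["a"]], 1)
  expect_equal(degree_centrality(g, "total")[["c"]], 0)
  expect_equal(degree_centrality(g, "total"),
    degree_centrality(g, "in") + degree_centrality(g, "out"))
})

test_that("weighted degree sums incident flows per direction", {
  labels <- c("x", "y", "z", "v")
  w <- named_matrix(rep(0, 16), labels)
  w["x", "v"] <- 3
  w["y", "v"] <- 4
  w["v", "z"] <- 5
  g <- net_from(w)
  expect_equal(weighted_degree(g, "in")[["v"]], 7)
  expect_equal(weighted_degree(g, "out")[["v"]], 5)
  expect_equal(weighted_degree(g, "total")[["v"]], 12)
})

test_that("closeness follows the per-reachable-set formula on hop distances", {
  g <- path_graph()
  cl <- closeness_centrality(g)
  expect_equal(cl[["a"]], 2 / 3)
  expect_equal(cl[["b"]], 1)
  expect_equal(cl[["c"]], 0) # no out-neighbours

  labels <- letters[1:3]
  complete <- named_matrix(rep(1, 9), labels)
  diag(complete) <- 0
  expect_equal(unname(closeness_centrality(net_from(complete))), rep(1, 3))
})

test_that("betweenness counts pair dependencies on directed hop-shortest paths", {
  g <- path_graph()
  b <- betweenness_centrality(g)
  expect_equal(unname(b), c(0, 1, 0))

  labels <- letters[1:4]
  complete <- named_matrix(rep(1, 16), labels)
  diag(complete) <- 0
  expect_equal(unname(betweenness_centrality(net_from(complete))), rep(0, 4))
})

test_that("clustering uses the undirected projection and zero for sparse neighbourhoods", {
  labels <- c("a", "b", "c")
  tri <- named_matrix(rep(0, 9), labels)
  tri["a", "b"] <- 1
  tri["b", "c"] <- 1
  tri["c", "a"] <- 1
  expect_equal(unname(clustering_coefficient(net_from(tri))), rep(1, 3))

  star <- named_matrix(rep(0, 25), c("hub", "l1", "l2", "l3", "l4"))
  star["hub", c("l1", "l2", "l3", "l4")] <- 1
  expect_equal(unname(clustering_coefficient(net_from(star))), rep(0, 5))
})

test_that("PageRank is uniform on cycles, sums to one, and validates damping", {
  labels <- sprintf("n%d", 1:5)
  cyc <- named_matrix(rep(0, 25), labels)
  for (i in 1:5) cyc[i, i %% 5 + 1] <- 2
  g <- net_from(cyc)
  pr <- pagerank_centrality(g)
  expect_equal(unname(pr), rep(0.2, 5), tolerance = 1e-10)
  expect_equal(sum(pr), 1, tolerance = 1e-8)
  expect_error(pagerank_centrality(g, damping = 1.2),
    class = "flownet_error_parameter")
  expect_error(pagerank_centrality(g, damping = 0),
    class = "flownet_error_parameter")
})

test_that("PageRank matches the dense linear solve and igraph on weighted digraphs", {
  withr::local_seed(99)
  for (rep in 1:20) {
    net <- random_flow_network(n = sample(3:8, 1))
    g <- build_network(net$matrix, net$roles)
    pr <- pagerank_centrality(g, tol = 1e-13)
    expect_equal(unname(pr), oracle_pagerank(net$weights), tolerance = 1e-8)
    pr_ig <- igraph::page_rank(g, damping = 0.85,
      weights = igraph::E(g)$weight)$vector
    expect_equal(unname(pr), unname(pr_ig), tolerance = 1e-6)
  }
})

test_that("path metrics equal brute-force enumeration on random digraphs", {
  withr::local_seed(7)
  for (rep in 1:40) {
    net <- random_flow_network()
    g <- build_network(net$matrix, net$roles)
    adj <- (net$weights > 0) * 1
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(adj),
      tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(g)), oracle_closeness(adj),
      tolerance = 1e-12)
    expect_equal(unname(clustering_coefficient(g)), oracle_clustering(adj),
      tolerance = 1e-12)
  }
})

test_that("isolated nodes score zero on every indicator", {
  labels <- c("a", "b", "iso")
  w <- named_matrix(rep(0, 9), labels)
  w["a", "b"] <- 3
  tab <- centrality_table(net_from(w))
  iso_row <- tab[tab$node == "iso", ]
  expect_true(iso_row$isolated)
  expect_equal(iso_row$degree_total, 0)
  expect_equal(iso_row$weighted_degree_total, 0)
  expect_equal(iso_row$closeness, 0)
  expect_equal(iso_row$betweenness, 0)
  expect_equal(iso_row$clustering, 0)
})

test_that("relabelling nodes permutes every metric vector identically", {
  withr::local_seed(21)
  for (rep in 1:10) {
    net <- random_flow_network(n = 7)
    w <- net$weights
    perm <- sample(7)
    w2 <- w[perm, perm]
    g1 <- net_from(w)
    g2 <- net_from(w2)
    t1 <- centrality_table(g1)
    t2 <- centrality_table(g2)
    reord <- match(t1$node[perm], t2$node)
    for (col in c("degree_total", "weighted_degree_total", "closeness",
      "betweenness", "pagerank", "clustering")) {
      expect_equal(t2[[col]][reord], t1[[col]][perm], tolerance = 1e-10)
    }
  }
})

test_that("adding an isolated node perturbs nothing but the PageRank teleport term", {
  withr::local_seed(5)
  net <- random_flow_network(n = 6, p = 0.4)
  w <- net$weights
  g1 <- net_from(w)
  w2 <- rbind(cbind(w, extra = 0), extra = 0)
  rownames(w2)[7] <- colnames(w2)[7] <- "zzz_iso"
  g2 <- net_from(w2)
  keep <- rownames(w)
  expect_equal(closeness_centrality(g2)[keep], closeness_centrality(g1)[keep])
  expect_equal(betweenness_centrality(g2)[keep], betweenness_centrality(g1)[keep])
  expect_equal(clustering_coefficient(g2)[keep], clustering_coefficient(g1)[keep])
  # with the larger teleport pool the old nodes' scores change only via 1/n
  pr2 <- pagerank_centrality(g2, tol = 1e-13)
  expect_equal(unname(pr2), oracle_pagerank(w2), tolerance = 1e-8)
})

test_that("repeated runs are bit-identical", {
  net <- generate_bipartite_network(fixture_tables("cost_2014"))
  g <- build_network(net$matrix, net$roles)
  expect_identical(centrality_table(g), centrality_table(g))
})
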