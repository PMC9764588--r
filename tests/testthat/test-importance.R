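make_table <- function(df) {
  # minimal centrality table for importance tests
  defaults <- data.frame(
    node = df$node,
    role = "financial_agents",
    degree_total = df$degree_total %||% rep(1, nrow(df))
  )
  for (col in c("weighted_degree_total", "closeness", "betweenness",
    "pagerank", "clustering")) {
    defaults[[col]] <- df[[col]] %||% rep(0, nrow(df))
  }
  defaults$isolated <- defaults$degree_total == 0
  class(defaults) <- c("centrality_table", "data.frame")
  defaults
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("min-max normalization maps extremes to 0 and 1 and preserves order", {
  expect_equal(min_max_normalize(c(5, 1, 9)), c(0.5, 0, 1))
  expect_equal(min_max_normalize(c(3, 3, 3)), c(0, 0, 0))
  expect_error(min_max_normalize(numeric(0)),
    class = "flownet_error_degenerate")
  expect_error(min_max_normalize(c(1, NA)),
    class = "flownet_error_nonnumeric")
  withr::local_seed(2)
  for (rep in 1:20) {
    x <- stats::rnorm(sample(2:30, 1))
    n <- min_max_normalize(x)
    expect_equal(order(x), order(n))
    expect_equal(range(n), c(0, 1))
  }
})

test_that("a node dominating every metric scores composite 1, the dominated node 0", {
  tab <- make_table(data.frame(
    node = c("big", "small"),
    weighted_degree_total = c(10, 1), closeness = c(1, 0.2),
    betweenness = c(5, 0), pagerank = c(0.8, 0.2), clustering = c(1, 0)
  ))
  imp <- combined_importance(tab)
  expect_equal(imp$importance[imp$node == "big"], 1)
  expect_equal(imp$importance[imp$node == "small"], 0)
  expect_equal(imp$rank, c(1L, 2L))
})

test_that("identical metrics give all-zero composites ranked by label", {
  tab <- make_table(data.frame(
    node = c("beta", "alpha", "gamma"),
    weighted_degree_total = c(4, 4, 4), closeness = c(1, 1, 1),
    betweenness = c(0, 0, 0), pagerank = c(1 / 3, 1 / 3, 1 / 3),
    clustering = c(0, 0, 0)
  ))
  imp <- combined_importance(tab)
  expect_equal(imp$importance, rep(0, 3))
  expect_equal(imp$node[order(imp$rank)], c("alpha", "beta", "gamma"))
  expect_error(combined_importance(tab, character(0)),
    class = "flownet_error_parameter")
  expect_error(combined_importance(tab, "eigenvector"),
    class = "flownet_error_parameter")
})

test_that("the fragmented-network rule selects weighted degree alone, strictly", {
  fragmented <- structure(list(isolated_share = 100 * 29 / 42),
    class = "network_summary")
  expect_equal(select_indices(fragmented), "weighted_degree")

  connected <- structure(list(isolated_share = 0), class = "network_summary")
  expect_length(select_indices(connected), 5)

  at_threshold <- structure(list(isolated_share = 50), class = "network_summary")
  expect_length(select_indices(at_threshold, 0.5), 5) # strict inequality

  expect_error(select_indices(connected, -0.1),
    class = "flownet_error_parameter")
  expect_error(select_indices(connected, 1.5),
    class = "flownet_error_parameter")
})

test_that("rank_actors orders by composite, breaks ties by label, respects top_k", {
  tab <- make_table(data.frame(
    node = c("zed", "ann", "mid"),
    weighted_degree_total = c(5, 5, 1)
  ))
  imp <- combined_importance(tab, "weighted_degree")
  top <- rank_actors(imp, 2)
  expect_equal(top$node, c("ann", "zed")) # tie broken alphabetically
  expect_equal(nrow(rank_actors(imp, 0)), 0)
  expect_equal(nrow(rank_actors(imp, 100)), 3)
  expect_error(rank_actors(imp, -1), class = "flownet_error_parameter")
})

test_that("isolated nodes are excluded from baselines and receive no rank", {
  tab <- make_table(data.frame(
    node = c("a", "b", "iso"),
    degree_total = c(2, 2, 0),
    weighted_degree_total = c(8, 2, 0)
  ))
  imp <- combined_importance(tab, "weighted_degree")
  expect_equal(imp$norm_weighted_degree[imp$node == "b"], 0) # min over non-isolated
  expect_true(is.na(imp$rank[imp$node == "iso"]))
  expect_equal(sort(imp$rank[imp$node != "iso"]), 1:2)
  expect_false("iso" %in% rank_actors(imp)$node)
})

test_that("raising one metric never lowers a node's composite (monotonicity)", {
  withr::local_seed(31)
  for (rep in 1:15) {
    n <- 6
    base <- data.frame(
      node = sprintf("n%d", 1:n),
      weighted_degree_total = stats::runif(n, 0, 10),
      closeness = stats::runif(n), betweenness = stats::runif(n, 0, 5),
      pagerank = stats::runif(n), clustering = stats::runif(n)
    )
    tab <- make_table(base)
    imp0 <- combined_importance(tab, rescale = "mean")
    v <- sample(n, 1)
    metric <- sample(c("weighted_degree_total", "closeness", "betweenness",
      "pagerank", "clustering"), 1)
    bumped <- base
    bumped[[metric]][v] <- bumped[[metric]][v] + stats::runif(1, 0.1, 3)
    imp1 <- combined_importance(make_table(bumped), rescale = "mean")
    expect_gte(imp1$importance[v] + 1e-12, imp0$importance[v])
  }
})

test_that("ranks are invariant to global rescaling of edge weights", {
  withr::local_seed(13)
  for (const in c(0.001, 7, 1e6)) {
    net <- random_flow_network(n = 8, p = 0.4)
    g1 <- build_network(net$matrix, net$roles)
    g2 <- build_network(flow_matrix(net$weights * const,
      labels = rownames(net$weights)), net$roles)
    imp1 <- combined_importance(centrality_table(g1))
    imp2 <- combined_importance(centrality_table(g2))
    expect_equal(imp2$importance, imp1$importance, tolerance = 1e-9)
    expect_equal(imp2$rank, imp1$rank)
    for (col in grep("^norm_", names(imp1), value = TRUE)) {
      expect_equal(imp2[[col]], imp1[[col]], tolerance = 1e-9)
    }
  }
})

test_that("weighted-degree-only ranking equals the raw weighted-degree ordering", {
  withr::local_seed(17)
  net <- random_flow_network(n = 9, p = 0.5)
  g <- build_network(net$matrix, net$roles)
  tab <- centrality_table(g)
  imp <- combined_importance(tab, "weighted_degree")
  active <- !tab$isolated
  raw_order <- order(-tab$weighted_degree_total[active], tab$node[active],
    method = "radix")
  expect_equal(order(imp$rank[active])[seq_len(sum(active))], raw_order)
})

test_that("composite attains 0 and 1 whenever raw metrics are non-constant", {
  withr::local_seed(23)
  for (rep in 1:10) {
    net <- random_flow_network(n = sample(4:9, 1), p = 0.5)
    g <- build_network(net$matrix, net$roles)
    tab <- centrality_table(g)
    active <- !tab$isolated
    if (sum(active) < 2) next
    imp <- combined_importance(tab)
    vals <- imp$importance[active]
    if (stats::var(rowSums(tab[active, c("weighted_degree_total", "closeness",
      "betweenness", "pagerank", "clustering")])) > 0) {
      expect_equal(max(vals), 1)
      expect_equal(min(vals), 0)
    }
  }
})
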