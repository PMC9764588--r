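#' Degree centrality (link counts)
#'
#' Number of links entering, leaving, or incident to each node. Weights are
#' ignored; `total = in + out`.
#'
#' @param g A financial network.
#' @param mode One of `"total"`, `"in"`, `"out"`.
#' @return Named numeric vector of per-node link counts.
#' @export
degree_centrality <- function(g, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  res <- igraph::degree(g, mode = switch(mode,
    total = "all", `in` = "in", out = "out"), loops = FALSE)
  as.numeric(res) |> stats::setNames(igraph::V(g)$name)
}

#' Weighted degree centrality (incident flow sums)
#'
#' Sum of the weights of the links entering, leaving, or incident to each
#' node. In a payer-provider network, in-weighted-degree is money received
#' and out-weighted-degree money paid. `total = in + out`.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector of per-node weight sums.
#' @export
weighted_degree <- function(g, mode = c("total", "in", "out")) {
  mode <- match.arg(mode)
  res <- igraph::strength(g, mode = switch(mode,
    total = "all", `in` = "in", out = "out"),
    loops = FALSE, weights = igraph::E(g)$weight)
  as.numeric(res) |> stats::setNames(igraph::V(g)$name)
}

#' Closeness centrality on hop-count shortest paths
#'
#' For node v with reachable set R(v) (directed hop-distance shortest paths,
#' excluding v itself), closeness is `|R(v)| / sum of distances to R(v)`, and
#' 0 when v reaches no other node. Computing per reachable set keeps the
#' index finite on disconnected graphs. Edge weights are flow magnitudes,
#' not distances, so they are ignored for path lengths.
#'
#' @param g A financial network.
#' @return Named numeric vector of per-node closeness values in \[0, 1\].
#' @export
closeness_centrality <- function(g) {
  res <- suppressWarnings(igraph::closeness(g, mode = "out",
    weights = NA, normalized = TRUE))
  res[!is.finite(res)] <- 0
  as.numeric(res) |> stats::setNames(igraph::V(g)$name)
}

#' Betweenness centrality on hop-count shortest paths
#'
#' Directed shortest-path betweenness by pair dependencies: for every ordered
#' pair (s, t) with s != v != t, the fraction of hop-shortest s-t paths that
#' pass through v, summed over pairs. Reported unnormalized; normalization is
#' done downstream when building the importance index.
#'
#' @param g A financial network.
#' @return Named numeric vector of per-node non-negative betweenness values.
#' @export
betweenness_centrality <- function(g) {
  res <- igraph::betweenness(g, directed = TRUE, weights = NA)
  as.numeric(res) |> stats::setNames(igraph::V(g)$name)
}

#' PageRank on weighted out-edge transitions
#'
#' Power iteration on the PageRank equations with weighted out-edge
#' transition probabilities: from node i, probability of moving to j is
#' `w_ij / sum_k w_ik`. Dangling nodes (no out-edges) redistribute their
#' mass uniformly over all nodes. Iteration stops when the L1 change falls
#' below `tol`; scores always sum to 1.
#'
#' @param g A non-empty financial network.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-9.
#' @param max_iter Maximum number of iterations; default 1000.
#' @return Named numeric vector of per-node probabilities summing to 1.
#' @export
pagerank_centrality <- function(g, damping = 0.85, tol = 1e-9,
                                max_iter = 1000) {
  if (!is.numeric(damping) || length(damping) != 1 ||
    damping <= 0 || damping >= 1) {
    abort_flownet("damping factor must be a single number in (0, 1)",
      "flownet_error_parameter")
  }
  n <- igraph::vcount(g)
  if (n == 0) {
    abort_flownet("PageRank is undefined on an empty graph",
      "flownet_error_degenerate")
  }
  w <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0)
    "weight" else NULL, sparse = FALSE)
  out_sum <- rowSums(w)
  dangling <- out_sum == 0
  trans <- w
  trans[!dangling, ] <- w[!dangling, , drop = FALSE] / out_sum[!dangling]
  x <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    x_new <- damping * (as.numeric(x %*% trans) + sum(x[dangling]) / n) +
      (1 - damping) / n
    if (sum(abs(x_new - x)) < tol) {
      x <- x_new
      break
    }
    x <- x_new
  }
  stats::setNames(x / sum(x), igraph::V(g)$name)
}

#' Local clustering coefficient on the undirected projection
#'
#' Triangles through a node divided by the number of neighbour pairs
#' `k(k-1)/2`, computed on the undirected, unweighted projection of the
#' network (reciprocal directed links collapse to one). Nodes with fewer
#' than two neighbours score 0.
#'
#' @param g A financial network.
#' @return Named numeric vector of per-node values in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  ug <- igraph::as_undirected(g, mode = "collapse")
  res <- igraph::transitivity(ug, type = "local", isolates = "zero",
    weights = NA)
  as.numeric(res) |> stats::setNames(igraph::V(g)$name)
}

#' Per-node table of the six micro indicators
#'
#' Computes degree (in/out/total), weighted degree (in/out/total), closeness,
#' betweenness, PageRank and the clustering coefficient for every node.
#'
#' @param g A financial network.
#' @param damping,tol PageRank settings, see [pagerank_centrality()].
#' @return A data frame of class `centrality_table` with one row per node:
#'   `node`, `role`, the six indicators (degree and weighted degree in all
#'   three modes), and a logical `isolated` column.
#' @export
centrality_table <- function(g, damping = 0.85, tol = 1e-9) {
  deg_tot <- degree_centrality(g, "total")
  tab <- data.frame(
    node = igraph::V(g)$name,
    role = igraph::V(g)$role %||% rep(NA_character_, igraph::vcount(g)),
    degree_in = degree_centrality(g, "in"),
    degree_out = degree_centrality(g, "out"),
    degree_total = deg_tot,
    weighted_degree_in = weighted_degree(g, "in"),
    weighted_degree_out = weighted_degree(g, "out"),
    weighted_degree_total = weighted_degree(g, "total"),
    closeness = closeness_centrality(g),
    betweenness = betweenness_centrality(g),
    pagerank = pagerank_centrality(g, damping = damping, tol = tol),
    clustering = clustering_coefficient(g),
    isolated = deg_tot == 0,
    row.names = NULL,
    check.names = FALSE
  )
  class(tab) <- c("centrality_table", "data.frame")
  tab
}
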