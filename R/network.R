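#' Build a directed weighted financial network from a flow matrix
#'
#' Every off-diagonal cell (i, j) with positive weight becomes one directed
#' edge i -> j of that weight (row = payer, column = payee). Zero-weight cells
#' are non-edges, so density and isolated-node counts are meaningful. Diagonal
#' cells (self-flows) are ignored with a warning; the analysis has no use for
#' self-loops. Nodes with no incident edge are retained as isolated nodes.
#'
#' @param m A [flow_matrix()].
#' @param roles Named character vector mapping every node label to a role
#'   category (see [role_categories()]).
#'
#' @return An [igraph::igraph] directed graph whose vertices carry `name` and
#'   `role` attributes and whose edges carry `weight`; graph attributes `year`
#'   and `unit` are copied from the flow matrix.
#' @export
#' @examples
#' w <- matrix(c(0, 7, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' roles <- c(a = "financial_sources", b = "financial_agents")
#' g <- build_network(flow_matrix(w), roles)
#' igraph::E(g)$weight
build_network <- function(m, roles) {
  stopifnot(inherits(m, "flow_matrix"))
  missing <- setdiff(m$labels, names(roles))
  if (length(missing) > 0) {
    abort_flownet(
      sprintf("no role category supplied for node '%s'", missing[1]),
      "flownet_error_missing_label"
    )
  }
  bad_role <- setdiff(unique(unname(roles[m$labels])), role_categories())
  if (length(bad_role) > 0) {
    abort_flownet(
      sprintf("unknown role category '%s'", bad_role[1]),
      "flownet_error_metadata"
    )
  }
  w <- m$weights
  n_self <- sum(diag(w) > 0)
  if (n_self > 0) {
    warning(sprintf("ignoring %d self-flow (diagonal) cell%s",
      n_self, if (n_self > 1) "s" else ""), call. = FALSE)
  }
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
    weighted = TRUE, diag = FALSE)
  igraph::V(g)$role <- unname(roles[m$labels])
  g <- igraph::set_graph_attr(g, "year", m$year)
  g <- igraph::set_graph_attr(g, "unit", m$unit)
  g
}

#' Identify isolated nodes
#'
#' @param g A financial network as returned by [build_network()].
#' @return Character vector of labels of nodes with no incident edge.
#' @export
isolated_nodes <- function(g) {
  igraph::V(g)$name[igraph::degree(g, mode = "all") == 0]
}

#' Macro indicators of a financial network
#'
#' Computes the whole-network (macro) indicators: size (nodes and edges),
#' density for directed graphs (`edges / (n * (n - 1))`), the number and
#' percentage share of isolated nodes, and the percentage of nodes in each
#' role category. Shares are kept as exact fractions; the print method rounds
#' them to whole percent for display.
#'
#' @param g A financial network as returned by [build_network()]; must have
#'   at least two nodes (density is undefined otherwise).
#'
#' @return An object of class `network_summary`: a list with `n_nodes`,
#'   `n_edges`, `density`, `total_weight`, `n_isolated`, `isolated_share`
#'   (percent, exact), and `role_shares` (named percent vector, exact).
#' @export
network_summary <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n < 2) {
    abort_flownet("network summary requires at least 2 nodes (density undefined)",
      "flownet_error_degenerate")
  }
  n_edges <- igraph::ecount(g)
  n_isolated <- sum(igraph::degree(g, mode = "all") == 0)
  roles <- igraph::V(g)$role %||% rep(NA_character_, n)
  role_counts <- table(factor(roles, levels = role_categories()))
  role_counts <- role_counts[role_counts > 0]
  structure(
    list(
      n_nodes = n,
      n_edges = n_edges,
      density = n_edges / (n * (n - 1)),
      total_weight = sum(igraph::E(g)$weight %||% numeric(0)),
      n_isolated = n_isolated,
      isolated_share = 100 * n_isolated / n,
      role_shares = stats::setNames(100 * as.numeric(role_counts) / n,
        names(role_counts)),
      year = igraph::graph_attr(g, "year")
    ),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat("<network_summary>\n")
  cat(sprintf("  nodes: %d   edges: %d   density: %.4f\n",
    x$n_nodes, x$n_edges, x$density))
  cat(sprintf("  isolated: %d (%d%%)   total weight: %s\n",
    x$n_isolated, round(x$isolated_share),
    format(x$total_weight, big.mark = ",")))
  if (length(x$role_shares) > 0) {
    cat("  role shares:",
      paste(sprintf("%s %d%%", names(x$role_shares), round(x$role_shares)),
        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export the edge list of a financial network as CSV
#'
#' Writes one row per edge with columns `source`, `target`, `weight`.
#'
#' @param g A financial network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("source", "target")
  utils::write.csv(el[, c("source", "target", "weight")], path,
    row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a financial network as GEXF 1.2 (Gephi interchange)
#'
#' Writes a GEXF 1.2 document with a directed weighted graph, node labels,
#' and a `role` node attribute, suitable for opening in Gephi.
#'
#' @param g A financial network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  meta <- xml2::xml_add_child(doc, "meta")
  xml2::xml_add_child(meta, "creator", "flownet")
  graph <- xml2::xml_add_child(doc, "graph",
    mode = "static", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "role",
    type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  labels <- igraph::V(g)$name
  roles <- igraph::V(g)$role %||% rep("", length(labels))
  for (i in seq_along(labels)) {
    node <- xml2::xml_add_child(nodes, "node",
      id = as.character(i - 1), label = labels[i])
    av <- xml2::xml_add_child(node, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0", value = roles[i])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_data_frame(g, what = "edges")
  idx <- stats::setNames(seq_along(labels) - 1L, labels)
  if (nrow(el) > 0) {
    for (i in seq_len(nrow(el))) {
      xml2::xml_add_child(edges, "edge",
        id = as.character(i - 1),
        source = as.character(idx[[el$from[i]]]),
        target = as.character(idx[[el$to[i]]]),
        weight = format(el$weight[i], scientific = FALSE, trim = TRUE))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
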