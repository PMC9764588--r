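IMPORTANCE_METRICS <- c(
  weighted_degree = "weighted_degree_total",
  closeness = "closeness",
  betweenness = "betweenness",
  pagerank = "pagerank",
  clustering = "clustering"
)

#' Min-max normalization
#'
#' Rescales a vector to \[0, 1\]: `(x - min) / (max - min)`. Order-preserving;
#' the maximum maps to 1 and the minimum to 0. A constant vector maps to all
#' zeros (rather than NaN), which keeps composite indices finite on
#' degenerate networks.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return Numeric vector of the same length in \[0, 1\].
#' @export
#' @examples
#' min_max_normalize(c(5, 1, 9)) # 0.5, 0, 1
min_max_normalize <- function(values) {
  if (length(values) == 0) {
    abort_flownet("cannot normalize an empty vector", "flownet_error_degenerate")
  }
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort_flownet("values to normalize must be finite numbers",
      "flownet_error_nonnumeric")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Select which indicators enter the importance index
#'
#' On fragmented networks — many isolated nodes, very low density — path-based
#' indicators degenerate, so only weighted degree is used; otherwise all five
#' indicators (weighted degree, closeness, betweenness, PageRank, clustering
#' coefficient) enter the combined index. The rule is strict: the fallback
#' triggers only when the isolated share exceeds the threshold.
#'
#' @param s A [network_summary()].
#' @param isolated_threshold Isolated-node share (fraction in \[0, 1\]) above
#'   which only weighted degree is used. Default 0.5.
#' @return Character vector of selected metric names.
#' @export
select_indices <- function(s, isolated_threshold = 0.5) {
  stopifnot(inherits(s, "network_summary"))
  if (!is.numeric(isolated_threshold) || length(isolated_threshold) != 1 ||
    isolated_threshold < 0 || isolated_threshold > 1) {
    abort_flownet("isolated_threshold must be a fraction in [0, 1]",
      "flownet_error_parameter")
  }
  if (s$isolated_share / 100 > isolated_threshold) {
    "weighted_degree"
  } else {
    names(IMPORTANCE_METRICS)
  }
}

#' Combined importance index over normalized indicators
#'
#' Each selected indicator is min-max normalized over the non-isolated nodes,
#' the normalized columns are summed, and the sum is rescaled so the top
#' actor scores exactly 1. Isolated nodes are excluded from the normalization
#' baselines (their zeros would otherwise pin every minimum) and receive no
#' rank; ties are broken lexicographically by node label.
#'
#' @param tab A [centrality_table()].
#' @param selected Metrics to combine; subset of `weighted_degree`,
#'   `closeness`, `betweenness`, `pagerank`, `clustering`. Typically the
#'   output of [select_indices()].
#' @param rescale How to map the summed composite back to \[0, 1\]:
#'   `"minmax"` (default) min-max rescales the sum; `"mean"` divides by the
#'   number of selected metrics.
#' @param year Optional year tag carried on the result.
#' @return A data frame of class `importance_ranking` with one row per node:
#'   `node`, `role`, one `norm_<metric>` column per selected metric,
#'   `importance` in \[0, 1\], and `rank` (1 = most important; NA for isolated
#'   nodes).
#' @export
combined_importance <- function(tab, selected = names(IMPORTANCE_METRICS),
                                rescale = c("minmax", "mean"), year = NULL) {
  stopifnot(inherits(tab, "data.frame"))
  rescale <- match.arg(rescale)
  if (length(selected) == 0) {
    abort_flownet("at least one metric must be selected",
      "flownet_error_parameter")
  }
  unknown <- setdiff(selected, names(IMPORTANCE_METRICS))
  if (length(unknown) > 0) {
    abort_flownet(
      sprintf(
        "unknown metric '%s'; valid metrics: %s",
        unknown[1], paste(names(IMPORTANCE_METRICS), collapse = ", ")
      ),
      "flownet_error_parameter"
    )
  }
  isolated <- if ("isolated" %in% names(tab)) tab$isolated
    else tab$degree_total == 0
  active <- !isolated
  out <- data.frame(node = tab$node,
    role = tab$role %||% rep(NA_character_, nrow(tab)))
  norm_cols <- character(0)
  for (metric in selected) {
    col <- IMPORTANCE_METRICS[[metric]]
    norm <- rep(NA_real_, nrow(tab))
    if (any(active)) {
      norm[active] <- min_max_normalize(tab[[col]][active])
    }
    norm_col <- paste0("norm_", metric)
    out[[norm_col]] <- norm
    norm_cols <- c(norm_cols, norm_col)
  }
  raw_sum <- rowSums(out[, norm_cols, drop = FALSE])
  importance <- rep(NA_real_, nrow(tab))
  if (any(active)) {
    importance[active] <- switch(rescale,
      minmax = min_max_normalize(raw_sum[active]),
      mean = raw_sum[active] / length(selected)
    )
  }
  out$importance <- importance
  out$rank <- rep(NA_integer_, nrow(tab))
  if (any(active)) {
    ord <- order(-importance[active], out$node[active], method = "radix")
    out$rank[active][ord] <- seq_len(sum(active))
  }
  attr(out, "year") <- year
  attr(out, "metrics") <- selected
  attr(out, "rescale") <- rescale
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Top actors by combined importance
#'
#' Orders the non-isolated nodes by descending importance (which, when only
#' weighted degree was selected, equals the ordering of the raw weighted
#' degrees), breaking ties alphabetically by label, and returns the first
#' `top_k`.
#'
#' @param r An [combined_importance()] ranking.
#' @param top_k Number of actors to return (`>= 0`); values larger than the
#'   number of non-isolated nodes return them all.
#' @return A data frame with the top `top_k` rows of the ranking, ordered by
#'   `rank`.
#' @export
rank_actors <- function(r, top_k = Inf) {
  stopifnot(inherits(r, "importance_ranking"))
  if (!is.numeric(top_k) || length(top_k) != 1 || top_k < 0) {
    abort_flownet("top_k must be a single non-negative number",
      "flownet_error_parameter")
  }
  ranked <- r[!is.na(r$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  out <- utils::head(ranked, top_k)
  rownames(out) <- NULL
  for (a in c("year", "metrics", "rescale")) attr(out, a) <- attr(r, a)
  out
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  year <- attr(x, "year")
  metrics <- attr(x, "metrics")
  cat(sprintf("<importance_ranking> %d nodes%s%s\n",
    nrow(x), if (!is.null(year) && !is.na(year)) paste0(", year ", year) else "",
    if (length(metrics) > 0)
      paste0(", metrics: ", paste(metrics, collapse = " + ")) else ""))
  print.data.frame(utils::head(x[order(is.na(x$rank), x$rank), ], n),
    row.names = FALSE, digits = 3)
  invisible(x)
}
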