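#' Construct a flow matrix
#'
#' A flow matrix is a square non-negative weighted adjacency matrix whose
#' rows are paying nodes and whose columns are receiving nodes. Cell (i, j)
#' holds the money (or referral count) flowing from node i to node j over a
#' reporting year.
#'
#' @param weights Square numeric matrix of non-negative, finite weights.
#' @param labels Character vector of node identifiers, one per row/column.
#'   Defaults to the row names of `weights`.
#' @param year Integer year tag (optional).
#' @param unit Free-text unit of the weights, e.g. `"million Rial"`.
#'
#' @return An object of class `flow_matrix` with elements `labels`,
#'   `weights` (the labelled matrix), `year` and `unit`.
#' @export
#' @examples
#' w <- matrix(c(0, 5, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' flow_matrix(w, year = 2014, unit = "million Rial")
flow_matrix <- function(weights, labels = rownames(weights), year = NA_integer_,
                        unit = "") {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    abort_flownet(
      sprintf(
        "flow matrix must be square; got %d rows and %d columns",
        nrow(weights), ncol(weights)
      ),
      "flownet_error_nonsquare"
    )
  }
  if (is.null(labels)) {
    abort_flownet("node labels are required (none supplied and no row names)",
      "flownet_error_labels")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(weights)) {
    abort_flownet("number of labels must equal matrix dimension",
      "flownet_error_labels")
  }
  if (anyDuplicated(labels)) {
    abort_flownet(
      sprintf("duplicate node label: '%s'", labels[duplicated(labels)][1]),
      "flownet_error_labels"
    )
  }
  if (!is.numeric(weights)) {
    abort_flownet("flow weights must be numeric", "flownet_error_nonnumeric")
  }
  storage.mode(weights) <- "double"
  if (anyNA(weights) || any(!is.finite(weights))) {
    abort_flownet("flow weights must be finite and non-missing",
      "flownet_error_nonnumeric")
  }
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    abort_flownet(
      sprintf(
        "negative weight %g at ('%s', '%s'); flows must be non-negative",
        weights[bad[1], bad[2]], labels[bad[1]], labels[bad[2]]
      ),
      "flownet_error_negative"
    )
  }
  dimnames(weights) <- list(labels, labels)
  structure(
    list(labels = labels, weights = weights,
      year = as.integer(year), unit = as.character(unit)),
    class = "flow_matrix"
  )
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat(sprintf(
    "<flow_matrix> %d nodes, total off-diagonal flow %s%s%s\n",
    length(x$labels),
    format(total_flow(x), big.mark = ","),
    if (nzchar(x$unit)) paste0(" ", x$unit) else "",
    if (!is.na(x$year)) paste0(", year ", x$year) else ""
  ))
  invisible(x)
}

#' Total off-diagonal flow of a flow matrix
#'
#' @param m A [flow_matrix()].
#' @return The sum of all off-diagonal weights (self-flows excluded).
#' @export
total_flow <- function(m) {
  stopifnot(inherits(m, "flow_matrix"))
  sum(m$weights) - sum(diag(m$weights))
}

#' Read a flow matrix and node metadata from CSV files
#'
#' The matrix CSV must have a header row of node labels and a first column of
#' node labels; row and column labels must agree in order. The metadata CSV
#' must have columns `id`, `label` and `role`, and must list every label that
#' appears in the matrix. Matching is by exact, case-sensitive label, never by
#' position. Files must use comma separators and period decimal marks.
#'
#' @param matrix_path Path to the adjacency-matrix CSV.
#' @param metadata_path Path to the node-metadata CSV (`id,label,role`).
#' @param year,unit Optional year tag and unit recorded on the matrix.
#'
#' @return A list with elements `matrix` (a [flow_matrix()]) and `roles`
#'   (named character vector mapping label to role category).
#' @export
read_flow_matrix <- function(matrix_path, metadata_path, year = NA_integer_,
                             unit = "") {
  if (!file.exists(matrix_path)) {
    abort_flownet(sprintf("matrix file not found: '%s'", matrix_path),
      "flownet_error_io")
  }
  if (!file.exists(metadata_path)) {
    abort_flownet(sprintf("metadata file not found: '%s'", metadata_path),
      "flownet_error_io")
  }
  raw <- utils::read.csv(matrix_path, check.names = FALSE,
    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) {
    abort_flownet("matrix CSV must have a label column plus weight columns",
      "flownet_error_nonsquare")
  }
  row_labels <- as.character(raw[[1]])
  col_labels <- colnames(raw)[-1]
  if (length(row_labels) != length(col_labels)) {
    abort_flownet(
      sprintf(
        "flow matrix must be square; got %d rows and %d columns",
        length(row_labels), length(col_labels)
      ),
      "flownet_error_nonsquare"
    )
  }
  mism <- which(row_labels != col_labels)
  if (length(mism) > 0) {
    i <- mism[1]
    abort_flownet(
      sprintf(
        "row and column labels differ at position %d: row '%s' vs column '%s'",
        i, row_labels[i], col_labels[i]
      ),
      "flownet_error_label_mismatch"
    )
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort_flownet(
      sprintf(
        "non-numeric weight '%s' at ('%s', '%s')",
        cells[bad[1], bad[2]], row_labels[bad[1]], col_labels[bad[2]]
      ),
      "flownet_error_nonnumeric"
    )
  }
  dimnames(num) <- list(row_labels, col_labels)
  m <- flow_matrix(num, labels = row_labels, year = year, unit = unit)

  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  needed <- c("id", "label", "role")
  if (!all(needed %in% colnames(meta))) {
    abort_flownet(
      sprintf(
        "metadata CSV must have columns %s",
        paste(sQuote(needed), collapse = ", ")
      ),
      "flownet_error_metadata"
    )
  }
  bad_role <- setdiff(unique(meta$role), role_categories())
  if (length(bad_role) > 0) {
    abort_flownet(
      sprintf(
        "unknown role category '%s'; valid categories: %s",
        bad_role[1], paste(role_categories(), collapse = ", ")
      ),
      "flownet_error_metadata"
    )
  }
  missing <- setdiff(m$labels, meta$label)
  if (length(missing) > 0) {
    abort_flownet(
      sprintf("matrix label '%s' is absent from the metadata file", missing[1]),
      "flownet_error_missing_label"
    )
  }
  roles <- stats::setNames(as.character(meta$role), meta$label)[m$labels]
  list(matrix = m, roles = roles)
}

#' Remove aggregate (total) rows and columns from a flow matrix
#'
#' NHA tables carry aggregate rows such as total current health expenditure
#' that duplicate the sum of the elementary nodes; they must be pruned before
#' network construction so edges are not double counted.
#'
#' @param m A [flow_matrix()].
#' @param aggregate_labels Character vector of labels to remove. May be empty,
#'   in which case `m` is returned unchanged.
#'
#' @return A [flow_matrix()] without the aggregate rows and columns; all
#'   remaining weights are unchanged.
#' @export
#' @examples
#' w <- diag(0, 3)
#' w[1, 2] <- 4
#' dimnames(w) <- list(c("a", "b", "Total"), c("a", "b", "Total"))
#' prune_aggregates(flow_matrix(w), "Total")
prune_aggregates <- function(m, aggregate_labels) {
  stopifnot(inherits(m, "flow_matrix"))
  aggregate_labels <- as.character(aggregate_labels)
  if (length(aggregate_labels) == 0) {
    return(m)
  }
  missing <- setdiff(aggregate_labels, m$labels)
  if (length(missing) > 0) {
    abort_flownet(
      sprintf("aggregate label '%s' not found in the flow matrix", missing[1]),
      "flownet_error_missing_label"
    )
  }
  keep <- !(m$labels %in% aggregate_labels)
  flow_matrix(m$weights[keep, keep, drop = FALSE],
    labels = m$labels[keep], year = m$year, unit = m$unit)
}
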