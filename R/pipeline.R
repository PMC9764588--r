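#' Pipeline configuration
#'
#' Collects every setting of an end-to-end run. Exactly one input source must
#' be given: a matrix/metadata CSV pair, a built-in fixture name, or a
#' synthetic NHA specification.
#'
#' @param matrix_path,metadata_path Paths to an adjacency-matrix CSV and a
#'   node-metadata CSV (both or neither).
#' @param fixture Name of a built-in marginal table, see [fixture_tables()].
#' @param synthetic An [nha_spec()], or a list of arguments for one.
#' @param aggregates Labels of aggregate rows/columns to prune before
#'   network construction.
#' @param isolated_threshold Isolated-share fraction above which only
#'   weighted degree enters the importance index (see [select_indices()]).
#' @param damping,tol PageRank settings.
#' @param rescale Composite rescaling mode, `"minmax"` or `"mean"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed applied to any synthetic generation.
#' @param export Which graph exports to write: subset of `"gexf"`, `"csv"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, metadata_path = NULL,
                            fixture = NULL, synthetic = NULL,
                            aggregates = character(),
                            isolated_threshold = 0.5, damping = 0.85,
                            tol = 1e-9, rescale = "minmax",
                            out_dir = "flownet-out", seed = 1L,
                            export = c("gexf", "csv")) {
  has_files <- !is.null(matrix_path) || !is.null(metadata_path)
  if (has_files && (is.null(matrix_path) || is.null(metadata_path))) {
    abort_flownet("matrix_path and metadata_path must be given together",
      "flownet_error_config")
  }
  n_sources <- sum(has_files, !is.null(fixture), !is.null(synthetic))
  if (n_sources != 1) {
    abort_flownet(
      "exactly one input source is required: matrix/metadata files, a fixture name, or a synthetic spec",
      "flownet_error_config"
    )
  }
  if (!is.null(synthetic) && !inherits(synthetic, "nha_spec")) {
    if (!is.list(synthetic)) {
      abort_flownet("synthetic must be an nha_spec or a list of nha_spec arguments",
        "flownet_error_config")
    }
    synthetic <- do.call(nha_spec, synthetic)
  }
  if (!is.null(fixture)) {
    fixture_tables(fixture) # validates the name
  }
  if (!rescale %in% c("minmax", "mean")) {
    abort_flownet("rescale must be 'minmax' or 'mean'", "flownet_error_config")
  }
  if (!is.numeric(isolated_threshold) || isolated_threshold < 0 ||
    isolated_threshold > 1) {
    abort_flownet("isolated_threshold must be in [0, 1]", "flownet_error_config")
  }
  bad_export <- setdiff(export, c("gexf", "csv"))
  if (length(bad_export) > 0) {
    abort_flownet(sprintf("unknown export format '%s'", bad_export[1]),
      "flownet_error_config")
  }
  structure(
    list(
      matrix_path = matrix_path, metadata_path = metadata_path,
      fixture = fixture, synthetic = synthetic,
      aggregates = as.character(aggregates),
      isolated_threshold = isolated_threshold, damping = damping, tol = tol,
      rescale = rescale, out_dir = out_dir, seed = as.integer(seed),
      export = export
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; unknown keys
#' are rejected before any computation.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_flownet(sprintf("config file not found: '%s'", path),
      "flownet_error_io")
  }
  cfg <- yaml::read_yaml(path)
  valid <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), valid)
  if (length(unknown) > 0) {
    abort_flownet(sprintf("unknown config key '%s'", unknown[1]),
      "flownet_error_config")
  }
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Loads or generates the flow matrix, prunes aggregate nodes, builds the
#' directed weighted network, computes macro indicators and the per-node
#' centrality table, selects indicators by the fragmented-network rule,
#' builds the combined importance ranking, and writes every artifact to the
#' output directory: `summary.csv`/`summary.json`, `centrality.csv`,
#' `importance.csv`, `edges.csv`, `network.gexf`, and a `manifest.json`
#' recording every effective parameter, the seed and the package version.
#' Identical configuration and seed produce identical outputs.
#'
#' @param cfg A [pipeline_config()] (or path to a YAML file for one).
#' @return Invisibly, a list with the in-memory results: `network`,
#'   `summary`, `centrality`, `importance`, `ranking` (top actors) and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) {
    cfg <- read_pipeline_config(cfg)
  }
  stopifnot(inherits(cfg, "pipeline_config"))
  message("flownet: loading input")
  if (!is.null(cfg$matrix_path)) {
    input <- read_flow_matrix(cfg$matrix_path, cfg$metadata_path)
  } else if (!is.null(cfg$fixture)) {
    input <- generate_bipartite_network(fixture_tables(cfg$fixture))
  } else {
    spec <- cfg$synthetic
    spec$seed <- cfg$seed
    input <- generate_nha_network(spec)
  }
  m <- prune_aggregates(input$matrix, cfg$aggregates)
  g <- build_network(m, input$roles)
  s <- network_summary(g)
  message(sprintf("flownet: network built (%d nodes, %d edges, density %.4f)",
    s$n_nodes, s$n_edges, s$density))
  tab <- centrality_table(g, damping = cfg$damping, tol = cfg$tol)
  selected <- select_indices(s, cfg$isolated_threshold)
  message(sprintf("flownet: indicators selected: %s",
    paste(selected, collapse = " + ")))
  imp <- combined_importance(tab, selected, rescale = cfg$rescale,
    year = igraph::graph_attr(g, "year"))
  ranking <- rank_actors(imp)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  write1 <- function(name, writer) {
    p <- file.path(cfg$out_dir, name)
    writer(p)
    paths[[name]] <<- p
  }
  write1("summary.csv", function(p) {
    utils::write.csv(data.frame(
      n_nodes = s$n_nodes, n_edges = s$n_edges, density = s$density,
      total_weight = s$total_weight, n_isolated = s$n_isolated,
      isolated_share = s$isolated_share
    ), p, row.names = FALSE)
  })
  write1("summary.json", function(p) {
    jsonlite::write_json(unclass(s), p, auto_unbox = TRUE, digits = NA)
  })
  write1("centrality.csv", function(p) {
    utils::write.csv(tab, p, row.names = FALSE)
  })
  write1("importance.csv", function(p) {
    utils::write.csv(as.data.frame(imp), p, row.names = FALSE)
  })
  if ("csv" %in% cfg$export) write1("edges.csv", function(p) write_edge_list(g, p))
  if ("gexf" %in% cfg$export) write1("network.gexf", function(p) write_gexf(g, p))
  write1("manifest.json", function(p) {
    manifest <- cfg
    manifest$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
    jsonlite::write_json(
      list(config = unclass(manifest), selected_metrics = selected,
        package = "flownet",
        version = as.character(utils::packageVersion("flownet"))),
      p, auto_unbox = TRUE, digits = NA, null = "null"
    )
  })
  message(sprintf("flownet: wrote %d artifacts to %s", length(paths),
    cfg$out_dir))
  invisible(list(network = g, summary = s, centrality = tab,
    importance = imp, ranking = ranking, paths = paths))
}

#' Compare actor ranks across years
#'
#' Given two or more importance rankings over a shared actor set (e.g. one
#' per reporting year), tabulates each actor's rank trajectory and flags rank
#' changes between the first and last year.
#'
#' @param rankings Named list of [combined_importance()] rankings; names are
#'   used as year tags (falling back to each ranking's own year attribute).
#' @return A data frame of class `rank_comparison`: `node`, one `rank_<year>`
#'   column per ranking, `rank_change` (last minus first; negative = moved
#'   up), and logical `changed`.
#' @export
compare_years <- function(rankings) {
  if (!is.list(rankings) || length(rankings) < 2) {
    abort_flownet("compare_years needs at least two rankings",
      "flownet_error_parameter")
  }
  tags <- names(rankings)
  if (is.null(tags) || any(!nzchar(tags))) {
    tags <- vapply(seq_along(rankings), function(i) {
      y <- attr(rankings[[i]], "year")
      if (is.null(y) || is.na(y)) as.character(i) else as.character(y)
    }, character(1))
  }
  shared <- Reduce(intersect, lapply(rankings, function(r) r$node))
  if (length(shared) == 0) {
    abort_flownet("rankings share no actor labels", "flownet_error_parameter")
  }
  out <- data.frame(node = sort(shared))
  for (i in seq_along(rankings)) {
    r <- rankings[[i]]
    out[[paste0("rank_", tags[i])]] <-
      r$rank[match(out$node, r$node)]
  }
  first <- out[[2]]
  last <- out[[length(rankings) + 1]]
  out$rank_change <- last - first
  out$changed <- !is.na(out$rank_change) & out$rank_change != 0
  class(out) <- c("rank_comparison", "data.frame")
  out
}
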