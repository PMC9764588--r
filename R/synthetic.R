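#' Specification of a synthetic NHA-style flow network
#'
#' Describes a four-dimension National Health Accounts network: financing
#' sources, financing agents, health service providers and functions, with
#' money flowing along selected category pairs. Defaults give the 52-node
#' layout (5 sources, 17 agents, 9 providers, 21 functions) with flows along
#' the canonical chain sources -> agents -> providers -> functions plus
#' direct agent -> function flows, and a dominant households -> direct
#' payments edge, mirroring the out-of-pocket channel that dominates
#' health financing in many middle-income systems.
#'
#' @param n_sources,n_agents,n_providers,n_functions Node counts per role
#'   category (non-negative integers; defaults 5, 17, 9, 21).
#' @param intensities Named non-negative numeric vector of flow intensities
#'   per ordered category pair, names of the form
#'   `"financial_sources->financial_agents"`. Pairs absent or zero carry no
#'   flow.
#' @param heavy_multiplier Multiplier (> 1 to guarantee dominance) applied to
#'   the households -> direct-payments edge relative to the largest other
#'   edge weight. Default 3.
#' @param connect_prob Probability that an admissible node pair carries a
#'   flow. Default 0.5.
#' @param meanlog,sdlog Log-normal parameters for edge weights before
#'   intensity scaling. Defaults `log(1000)` and 1 (weights in units of
#'   million Rial).
#' @param seed Integer random seed; identical spec + seed give identical
#'   output.
#' @return An object of class `nha_spec`.
#' @export
nha_spec <- function(n_sources = 5, n_agents = 17, n_providers = 9,
                     n_functions = 21,
                     intensities = c(
                       "financial_sources->financial_agents" = 1,
                       "financial_agents->health_providers" = 1,
                       "health_providers->functions" = 1,
                       "financial_agents->functions" = 1
                     ),
                     heavy_multiplier = 3, connect_prob = 0.5,
                     meanlog = log(1000), sdlog = 1, seed = 1L) {
  counts <- c(n_sources, n_agents, n_providers, n_functions)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_flownet("role category counts must be non-negative integers",
      "flownet_error_parameter")
  }
  if (length(intensities) > 0 &&
    (is.null(names(intensities)) || any(!nzchar(names(intensities))))) {
    abort_flownet("intensities must be a named vector ('from->to' names)",
      "flownet_error_parameter")
  }
  if (any(intensities < 0)) {
    abort_flownet("flow intensities must be non-negative",
      "flownet_error_parameter")
  }
  nha_cats <- role_categories()[1:4]
  for (nm in names(intensities)) {
    parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !all(parts %in% nha_cats)) {
      abort_flownet(
        sprintf("invalid intensity pair name '%s'", nm),
        "flownet_error_parameter"
      )
    }
  }
  if (connect_prob < 0 || connect_prob > 1) {
    abort_flownet("connect_prob must be in [0, 1]", "flownet_error_parameter")
  }
  structure(
    list(
      counts = stats::setNames(as.integer(counts), nha_cats),
      intensities = intensities, heavy_multiplier = heavy_multiplier,
      connect_prob = connect_prob, meanlog = meanlog, sdlog = sdlog,
      seed = as.integer(seed)
    ),
    class = "nha_spec"
  )
}

nha_labels <- function(counts) {
  mk <- function(n, first, stem) {
    if (n == 0) return(character(0))
    c(first, if (n > 1) sprintf("%s %02d", stem, seq_len(n - 1)))
  }
  list(
    financial_sources = mk(counts[["financial_sources"]], "Households", "Source"),
    financial_agents = mk(counts[["financial_agents"]], "Direct payments", "Agent"),
    health_providers = if (counts[["health_providers"]] > 0)
      sprintf("Provider %02d", seq_len(counts[["health_providers"]]))
      else character(0),
    functions = if (counts[["functions"]] > 0)
      sprintf("Function %02d", seq_len(counts[["functions"]]))
      else character(0)
  )
}

#' Generate a synthetic NHA flow network
#'
#' Draws a flow matrix whose flows run only along the category pairs with
#' positive intensity. Each admissible (payer, payee) pair carries a flow
#' with probability `connect_prob`; weights are log-normal scaled by the
#' pair's intensity. The households -> direct-payments edge is always present
#' (when the sources -> agents intensity is positive) and set to
#' `heavy_multiplier` times the largest other weight, so it is the single
#' largest flow whenever the multiplier exceeds 1. Output is deterministic
#' under the spec's seed.
#'
#' @param spec An [nha_spec()].
#' @return A list with elements `matrix` (a [flow_matrix()]) and `roles`
#'   (named character vector), ready for [build_network()].
#' @export
#' @examples
#' net <- generate_nha_network(nha_spec(seed = 7))
#' length(net$matrix$labels) # 52
generate_nha_network <- function(spec) {
  stopifnot(inherits(spec, "nha_spec"))
  labels_by_cat <- nha_labels(spec$counts)
  active <- names(spec$intensities)[spec$intensities > 0]
  for (nm in active) {
    parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
    if (spec$counts[[parts[1]]] == 0 || spec$counts[[parts[2]]] == 0) {
      abort_flownet(
        sprintf("category pair '%s' has positive intensity but an empty side", nm),
        "flownet_error_parameter"
      )
    }
  }
  labels <- unlist(labels_by_cat, use.names = FALSE)
  roles <- stats::setNames(
    rep(names(labels_by_cat), lengths(labels_by_cat)), labels)
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  withr::with_seed(spec$seed, {
    for (nm in active) {
      parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
      from <- labels_by_cat[[parts[1]]]
      to <- labels_by_cat[[parts[2]]]
      for (i in from) {
        for (j in to) {
          if (i != j && stats::runif(1) < spec$connect_prob) {
            w[i, j] <- spec$intensities[[nm]] *
              stats::rlnorm(1, spec$meanlog, spec$sdlog)
          }
        }
      }
    }
  })
  src_agents <- "financial_sources->financial_agents"
  if (src_agents %in% active && spec$heavy_multiplier > 0) {
    heavy_from <- labels_by_cat$financial_sources[1]
    heavy_to <- labels_by_cat$financial_agents[1]
    w[heavy_from, heavy_to] <- 0
    w[heavy_from, heavy_to] <- spec$heavy_multiplier * max(w, 1)
  }
  list(
    matrix = flow_matrix(w, labels = labels, unit = "million Rial (synthetic)"),
    roles = roles
  )
}

#' Specification of a bipartite insurer-provider network
#'
#' Describes a payer-provider network by its marginals: each insurer's total
#' payment (or referral) volume and each provider's total receipts, plus a
#' number of isolated complementary-insurer nodes for which no transaction
#' data exists. Insurer and provider totals must balance (money paid equals
#' money received).
#'
#' @param insurers Named non-negative integer vector: insurer label -> total
#'   out-flow.
#' @param providers Named non-negative integer vector: provider label ->
#'   total in-flow. Must sum to the same grand total as `insurers`.
#' @param n_isolated Number of isolated complementary-insurer nodes
#'   (default 0).
#' @param isolated_prefix Label stem for the isolated nodes (default "CIO").
#' @param year,unit Year tag and unit recorded on generated matrices.
#' @param seed Integer seed, kept for interface uniformity; the allocation
#'   is deterministic.
#' @return An object of class `bipartite_spec`.
#' @export
bipartite_spec <- function(insurers, providers, n_isolated = 0,
                           isolated_prefix = "CIO", year = NA_integer_,
                           unit = "", seed = 1L) {
  if (is.null(names(insurers)) || is.null(names(providers))) {
    abort_flownet("insurer and provider marginals must be named vectors",
      "flownet_error_parameter")
  }
  if (any(insurers < 0) || any(providers < 0)) {
    abort_flownet("marginals must be non-negative", "flownet_error_negative")
  }
  if (n_isolated < 0) {
    abort_flownet("n_isolated must be non-negative", "flownet_error_parameter")
  }
  ti <- sum(insurers)
  tp <- sum(providers)
  if (ti != tp) {
    abort_flownet(
      sprintf(
        "marginal sums must balance: insurer total %s != provider total %s",
        format(ti, big.mark = ","), format(tp, big.mark = ",")
      ),
      "flownet_error_conservation"
    )
  }
  structure(
    list(
      insurers = insurers, providers = providers,
      n_isolated = as.integer(n_isolated), isolated_prefix = isolated_prefix,
      year = as.integer(year), unit = unit, seed = as.integer(seed)
    ),
    class = "bipartite_spec"
  )
}

# Proportional allocation w_ij = r_i c_j / T, made integer with exact
# marginals: row-wise largest-remainder rounding fixes every row sum, then
# single-unit transfers between surplus and deficit columns (within the row
# holding the largest cell of the surplus column; row-major ties) fix the
# column sums without disturbing the rows.
allocate_integer_matrix <- function(r, c) {
  n_r <- length(r)
  n_c <- length(c)
  total <- sum(r)
  w <- matrix(0L, n_r, n_c)
  if (total == 0) {
    return(w)
  }
  for (i in seq_len(n_r)) {
    ideal <- r[i] * c / total
    base <- floor(ideal)
    short <- r[i] - sum(base)
    if (short > 0) {
      frac <- ideal - base
      top <- order(-frac, seq_len(n_c), method = "radix")[seq_len(short)]
      base[top] <- base[top] + 1
    }
    w[i, ] <- base
  }
  col_dev <- colSums(w) - c
  while (any(col_dev > 0)) {
    j <- which(col_dev > 0)[1]
    k <- which(col_dev < 0)[1]
    i <- which.max(w[, j])
    w[i, j] <- w[i, j] - 1L
    w[i, k] <- w[i, k] + 1L
    col_dev[j] <- col_dev[j] - 1L
    col_dev[k] <- col_dev[k] + 1L
  }
  storage.mode(w) <- "double"
  w
}

#' Generate a bipartite insurer-provider network with exact marginals
#'
#' Produces an integer flow matrix whose insurer row sums and provider column
#' sums equal the requested marginals exactly, by proportional allocation
#' followed by largest-remainder integer correction, plus the requested number
#' of edgeless complementary-insurer nodes.
#'
#' @param spec A [bipartite_spec()].
#' @return A list with elements `matrix` (a [flow_matrix()]) and `roles`.
#' @export
#' @examples
#' spec <- bipartite_spec(c(A = 10), c(P = 10))
#' generate_bipartite_network(spec)$matrix$weights
generate_bipartite_network <- function(spec) {
  stopifnot(inherits(spec, "bipartite_spec"))
  ins <- names(spec$insurers)
  prov <- names(spec$providers)
  iso <- if (spec$n_isolated > 0)
    sprintf("%s %02d", spec$isolated_prefix, seq_len(spec$n_isolated))
    else character(0)
  labels <- c(ins, prov, iso)
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  w[ins, prov] <- allocate_integer_matrix(as.numeric(spec$insurers),
    as.numeric(spec$providers))
  roles <- stats::setNames(
    c(rep("insurer", length(ins)), rep("provider", length(prov)),
      rep("complementary_insurer", length(iso))),
    labels
  )
  list(
    matrix = flow_matrix(w, labels = labels, year = spec$year,
      unit = spec$unit),
    roles = roles
  )
}

#' Built-in insurer-provider marginal tables
#'
#' Returns bipartite specifications whose marginals are the published
#' weighted degrees of the Iranian basic-insurance cost networks (2014, 2016,
#' 2018, in millions of Rials) and the 2014 referral-rate network, each with
#' 29 isolated complementary-insurer nodes. The referral yearbooks for 2016
#' and 2018 fail the payer/receiver balance by one unit (an apparent source
#' rounding artifact), so no fixture is provided for them. The referral table
#' reports 10 provider types (no separate health-centre row), the cost tables
#' 11.
#'
#' @param name Optional fixture name; one of `"cost_2014"`, `"cost_2016"`,
#'   `"cost_2018"`, `"referral_2014"`. When omitted, all fixtures are
#'   returned as a named list.
#' @return A [bipartite_spec()] (when `name` is given) or a named list of
#'   them.
#' @export
#' @examples
#' fixture_tables("cost_2014")$insurers
fixture_tables <- function(name = NULL) {
  cost_providers <- function(hosp, gps, sps, dent, pharm, lab, radio, rehab,
                             dial, oth, hc) {
    c(
      "Hospitals and limited surgery centers" = hosp, "GPs" = gps,
      "SPs" = sps, "Dentists" = dent, "Pharmacies" = pharm,
      "Lab centers" = lab, "Radiology centers" = radio,
      "Rehabilitation centers" = rehab, "Dialysis centers" = dial,
      "Others centers" = oth, "Health Centers" = hc
    )
  }
  fixtures <- list(
    cost_2014 = bipartite_spec(
      insurers = c(IHIO = 103226078, SSO = 77381064),
      providers = cost_providers(92423700, 14104510, 15669790, 3074741,
        22394950, 4373950, 4767880, 2328426, 3380086, 733409, 17355700),
      n_isolated = 29, year = 2014, unit = "million Rial"
    ),
    cost_2016 = bipartite_spec(
      insurers = c(IHIO = 148175449, SSO = 128463267),
      providers = cost_providers(136052900, 20552980, 26064290, 4920481,
        37499400, 7774520, 9720970, 4552822, 4743417, 1097236, 23659700),
      n_isolated = 29, year = 2016, unit = "million Rial"
    ),
    cost_2018 = bipartite_spec(
      insurers = c(IHIO = 142412786, SSO = 137230563),
      providers = cost_providers(130314600, 21531130, 26921640, 5256980,
        42089200, 7611760, 9410370, 5475619, 6766031, 1354319, 22911700),
      n_isolated = 29, year = 2018, unit = "million Rial"
    ),
    referral_2014 = bipartite_spec(
      insurers = c(SSO = 258736373, IHIO = 146452507),
      providers = c(
        "Pharmacies" = 114906573, "SPs" = 99141152, "GPs" = 98718114,
        "Lab centers" = 37303404, "Radiology centers" = 24821944,
        "Dialysis centers" = 8839299,
        "Hospitals and limited surgery centers" = 7978609,
        "Dentists" = 7399975, "Others centers" = 5268550,
        "Rehabilitation centers" = 811260
      ),
      n_isolated = 29, year = 2014, unit = "referrals"
    )
  )
  if (is.null(name)) {
    return(fixtures)
  }
  if (!name %in% names(fixtures)) {
    abort_flownet(
      sprintf(
        "unknown fixture '%s'; available: %s",
        name, paste(names(fixtures), collapse = ", ")
      ),
      "flownet_error_parameter"
    )
  }
  fixtures[[name]]
}
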