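#' Role categories recognised by flownet
#'
#' The four NHA dimensions (financing sources, financing agents, health
#' service providers, functions) plus the three bipartite payer-provider
#' roles (insurer, provider, complementary insurer).
#'
#' @return Character vector of the seven valid role category names.
#' @export
#' @examples
#' role_categories()
role_categories <- function() {
  c(
    "financial_sources", "financial_agents", "health_providers", "functions",
    "insurer", "provider", "complementary_insurer"
  )
}

# classed errors so callers can distinguish validation failures
abort_flownet <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    list(message = message, call = call),
    class = c(class, "flownet_error", "error", "condition")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
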