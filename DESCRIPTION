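Package: flownet
Title: Financial Flow Network Analysis for Health Accounts and Insurance Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds role-annotated directed weighted networks from financial
    flow matrices such as National Health Accounts (NHA) tables and
    insurer-provider cost or referral matrices, computes macro network
    indicators (size, density, isolated share, role shares) and per-node
    centrality indicators (degree, weighted degree, closeness, betweenness,
    PageRank, clustering coefficient), and ranks actors by a combined
    importance index built from min-max normalized indicators. Includes
    synthetic generators that emulate the structure of NHA flow matrices and
    of bipartite payer-provider matrices with prescribed integer marginals,
    so the whole pipeline is testable without access to the source data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
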