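---
title: "Analysing financial flow networks in health insurance ecosystems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing financial flow networks in health insurance ecosystems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flownet)
```

## The model

`flownet` analyses money- and referral-flow systems as directed weighted
graphs. The input is a square flow matrix: rows are paying nodes, columns
receiving nodes, and cell (i, j) is the volume flowing from i to j over a
reporting year — currency for National Health Accounts (NHA) and
insurer-provider cost tables, visit counts for referral tables. Every
positive off-diagonal cell becomes one directed edge of that weight;
zero cells are non-edges, not zero-weight edges, which is what makes network
density and the isolated-node count meaningful. Diagonal cells (self-flows)
are dropped with a warning: a self-payment carries no information about the
relations between actors. Nodes carry one of seven role categories — the
four NHA dimensions (financing sources, financing agents, health service
providers, functions) or the three payer-provider roles (insurer, provider,
complementary insurer).

The analysis has two levels. Macro indicators describe the whole network:
node and edge counts, directed density $|E| / (n(n-1))$, and the isolated
and per-role node shares. Shares are kept as exact fractions internally and
rounded to whole percent only for display. Micro indicators describe nodes:

* **Degree** and **weighted degree**, each split into in / out / total.
  Weighted degree is the sum of incident edge weights — in a payer-provider
  network, an insurer's out-weighted-degree is the money it paid and a
  provider's in-weighted-degree the money it received. This reading makes
  the two sides of a bipartite network balance exactly (money paid equals
  money received), which the published insurer/provider tables satisfy.
* **Closeness** and **betweenness** on hop-count shortest paths. Edge
  weights here are flow magnitudes, not distances; treating a large payment
  as a long distance would invert importance, so path computations ignore
  weights. (A distance-as-inverse-flow variant would be a reasonable
  extension but is deliberately not the default.) Closeness is computed per
  reachable set, $|R(v)| / \sum_{u \in R(v)} d(v, u)$ with closeness 0 for a
  node that reaches nobody, so disconnected graphs need no infinite-distance
  convention. Betweenness is the unnormalized sum of pair dependencies
  $\sigma_{st}(v)/\sigma_{st}$; normalization happens later, in the
  importance index.
* **PageRank** with weighted out-edge transition probabilities, damping
  0.85, convergence when the L1 change of the score vector falls below
  `tol = 1e-9` (at most 1000 iterations), and dangling nodes redistributing
  their mass uniformly. The defaults mirror the common settings of
  general-purpose graph software; the damping factor must lie strictly
  inside (0, 1).
* **Clustering coefficient** on the undirected, unweighted projection:
  triangles through a node over $k(k-1)/2$ neighbour pairs, 0 when $k < 2$.
  Directed triangle taxonomies exist, but no single convention is standard
  for financial networks; the projection is the least surprising choice and
  is isolated behind one function.

## The combined importance index

To rank actors, selected indicators are min-max normalized,
$x' = (x - \min x) / (\max x - \min x)$, summed, and the sum rescaled to
[0, 1]. Three degenerate-input rules matter in practice:

* A constant column normalizes to all zeros rather than NaN, keeping
  composites finite on degenerate networks.
* Isolated nodes are excluded from the normalization baselines and receive
  no rank. In a fragmented network the isolated nodes' zeros would otherwise
  pin every column minimum, compressing the informative part of each scale.
* Ties are broken lexicographically by node label so rankings are
  reproducible.

The summed composite could reach the number of selected metrics, so it is
mapped back to [0, 1]. Two mappings are offered: min-max rescaling of the
sum (default), and division by the number of metrics. Both send the top
actor to at most 1; min-max is the default because it always awards the top
actor exactly 1.00, matching how published actor tables present the index.
The choice is a `rescale` argument, and rankings are identical under both
because the maps are monotone.

Normalization is always per network and per year. Values from different
years are never pooled into one min-max baseline: each year's table is a
self-contained ranking, and cross-year comparison is done on ranks
(`compare_years()`), not on scores.

**The fragmented-network rule.** When most nodes are isolated, path-based
indicators carry almost no signal — nearly all closeness, betweenness and
clustering values are 0, and PageRank collapses toward the teleport term. If
the isolated share exceeds a threshold (default 0.5, strict inequality),
`select_indices()` therefore selects weighted degree as the sole indicator;
otherwise all five enter the index. The strictness matters only exactly at
the boundary and is fixed for reproducibility.

## The synthetic generators

The NHA flow matrices and insurer yearbook tables this kind of analysis
consumes are typically not deposited, so the package ships two generators
that reproduce the *structure* the analysis assumes; every pipeline stage is
tested against them.

**Bipartite payer-provider networks** (`generate_bipartite_network()`) are
defined by their marginals: each insurer's total payments and each
provider's total receipts, which must balance. The generator allocates
integer cell weights proportionally, $w_{ij} = r_i c_j / T$, then makes each
row exact by largest-remainder rounding (ties broken in column order) and
repairs column sums by moving single units between surplus and deficit
columns within the row holding the surplus column's largest cell. The result
reproduces the requested integer marginals *exactly*, which is the property
the analysis needs: an actor's weighted degree in the rebuilt network equals
its published marginal, regardless of how the interior cells were split.
Iterative proportional fitting alone would only approximate integer
marginals. The allocation is fully deterministic; the spec's `seed` field is
kept for interface uniformity but no randomness is consumed. Requested
isolated complementary-insurer nodes are appended edgeless.

`fixture_tables()` hard-codes the published weighted-degree marginals of the
Iranian basic-insurance cost networks for 2014, 2016 and 2018 (millions of
Rials) and the 2014 referral network, each with 2 insurers (IHIO, SSO) and
29 isolated complementary insurers. The cost tables list 11 provider types;
the referral table lists 10 (it has no separate health-centre row). The
referral yearbook columns for 2016 and 2018 fail payer/receiver balance by
exactly one unit — an apparent rounding artifact in the source — and are
deliberately not shipped as fixtures rather than silently "corrected".

**NHA-style networks** (`generate_nha_network()`) emulate a 52-node,
four-category accounting network: 5 financing sources, 17 financing agents,
9 providers and 21 functions, with flows along the canonical chain
sources → agents → providers → functions plus direct agent → function
flows. Each admissible ordered node pair carries a flow with probability
`connect_prob` (default 0.5 — dense within blocks, as accounting matrices
are, while leaving enough zero cells to exercise the non-edge logic);
weights are log-normal (`meanlog = log(1000)`, `sdlog = 1`, i.e. typical
flows around a thousand million Rials with heavy right tail — flow volumes
are positive and strongly right-skewed) scaled by a per-category-pair
intensity. The households → direct-payments edge is then set to
`heavy_multiplier` (default 3) times the largest other weight, reproducing
the single dominant out-of-pocket channel that characterises
household-financed systems. Generation is deterministic under the spec's
seed.

What the generators do **not** emulate: realistic magnitudes beyond the
published marginal tables, cross-category flows outside the default chain
(real NHA matrices contain some), longitudinal correlation between years,
and any behavioural structure. Tests passing on synthetic data therefore
demonstrate that the pipeline's computations are correct and its invariants
hold — not that substantive conclusions about any real financing system
would be robust.

## Numerical conventions and edge cases

* Matrix CSVs must be comma-separated UTF-8 with period decimal marks. Some
  published tables use "/" as the decimal separator; convert before loading
  — the reader deliberately rejects such cells as non-numeric rather than
  guessing.
* Labels are case-sensitive exact strings and all matching is by label,
  never by file position.
* Validation failures are classed conditions (`flownet_error_nonsquare`,
  `flownet_error_negative`, `flownet_error_missing_label`, ...) naming the
  first offending label or cell, so callers can distinguish them.
* Aggregate total rows (e.g. "total current health expenditure") must be
  pruned with `prune_aggregates()` before network construction; they
  duplicate the elementary flows and would double-count every edge.
* A network summary requires at least 2 nodes (density is undefined on
  fewer); PageRank requires a non-empty graph; normalizing an empty vector
  is an error.
* All computations are deterministic: repeated runs are bit-identical, and
  `run_pipeline()` writes byte-identical artifacts under identical
  configuration and seed.

## Testing approach and problem sizes

Path-based centralities are verified against brute-force oracles that share
no code with the implementation: hop distances and shortest-path counts are
read off powers of the binary adjacency matrix (the first power at which a
walk exists gives the distance; the walk count at that power is the
shortest-path count), betweenness is accumulated from pair dependencies over
these counts, clustering from explicit neighbour-pair enumeration, and
PageRank from a dense linear-system solve. The equivalence suite runs 200
random digraphs of up to 10 nodes — small enough for exhaustive enumeration
to be trustworthy, large enough to hit branching shortest paths,
disconnected pairs and dangling nodes — and requires exact agreement
(PageRank to 1e-8). Marginal fidelity of the bipartite generator is checked
over 100 random integer marginal specifications, and the published cost and
referral tables are re-derived through the conservation identity: given the
provider column and one insurer's total, the other insurer's weighted degree
is forced, and must equal its published value.

## Limitations

* Closeness conventions differ across graph software (per-component
  normalization, harmonic closeness, in- vs out-distance); results are
  comparable across runs of this package, not necessarily across tools.
* The importance index inherits the usual caveats of composite indicators:
  equal implicit weighting of the selected metrics and sensitivity of
  min-max normalization to outliers.
* The bipartite generator's interior cells are one of many matrices
  consistent with the marginals; only marginal-determined quantities
  (weighted degrees, totals, isolation structure) should be interpreted.
* Rankings on fragmented networks rest on weighted degree alone, i.e. on
  volume, not position.
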