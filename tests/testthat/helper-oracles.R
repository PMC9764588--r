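# Brute-force oracles built on matrix powers, independent of the package's
# (igraph-backed) shortest-path machinery. For a binary adjacency matrix A,
# (A^L)[s, t] counts walks of length L; the first L at which it becomes
# positive is the hop distance, and the walk count at that L is the number of
# shortest paths (a minimal-length walk cannot revisit a node).

oracle_paths <- function(adj) {
  n <- nrow(adj)
  a <- (adj > 0) * 1
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(d) <- 0
  diag(sigma) <- 1
  pow <- diag(1, n)
  for (len in seq_len(max(n - 1, 1))) {
    pow <- pow %*% a
    newly <- is.infinite(d) & pow > 0
    d[newly] <- len
    sigma[newly] <- pow[newly]
  }
  list(d = d, sigma = sigma)
}

oracle_closeness <- function(adj) {
  sp <- oracle_paths(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    reach <- setdiff(which(is.finite(sp$d[v, ])), v)
    if (length(reach) == 0) 0 else length(reach) / sum(sp$d[v, reach])
  }, numeric(1))
}

# pair-dependency betweenness: sum over ordered (s, t) of the fraction of
# shortest s-t paths through v, using sigma(s,v) * sigma(v,t) when the
# distances compose
oracle_betweenness <- function(adj) {
  sp <- oracle_paths(adj)
  n <- nrow(adj)
  b <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || !is.finite(sp$d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(sp$d[s, v]) && is.finite(sp$d[v, t]) &&
          sp$d[s, v] + sp$d[v, t] == sp$d[s, t]) {
          b[v] <- b[v] + sp$sigma[s, v] * sp$sigma[v, t] / sp$sigma[s, t]
        }
      }
    }
  }
  b
}

# triangle / neighbour-pair enumeration on the undirected projection
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  u <- ((adj + t(adj)) > 0) * 1
  diag(u) <- 0
  vapply(seq_len(n), function(v) {
    nb <- which(u[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (u[nb[i], nb[j]] > 0) tri <- tri + 1
      }
    }
    tri / (k * (k - 1) / 2)
  }, numeric(1))
}

# PageRank as the exact solution of the linear system
# x = damping * t(M) x + (1 - damping) / n, with weighted transitions and
# uniform dangling redistribution inside M
oracle_pagerank <- function(w, damping = 0.85) {
  n <- nrow(w)
  m <- matrix(1 / n, n, n)
  out_sum <- rowSums(w)
  live <- out_sum > 0
  m[live, ] <- w[live, , drop = FALSE] / out_sum[live]
  solve(diag(n) - damping * t(m), rep((1 - damping) / n, n))
}

# random weighted digraph as a flow matrix + uniform role map
random_flow_network <- function(n = sample(2:10, 1), p = 0.3) {
  labels <- sprintf("n%02d", seq_len(n))
  w <- matrix(stats::rbinom(n * n, 1, p) *
    round(stats::runif(n * n, 1, 50), 2), n, n)
  diag(w) <- 0
  dimnames(w) <- list(labels, labels)
  roles <- stats::setNames(rep("financial_agents", n), labels)
  list(matrix = flow_matrix(w, labels = labels), roles = roles,
    weights = w)
}
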