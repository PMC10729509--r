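# Independent oracles and small graph builders used across the suite.
# Everything here deliberately avoids the package's Brandes accumulation
# and phyper-backed tail so that implementation and oracle stay on
# separate routes.

# Edge table for a named undirected graph given as a 2-column matrix of
# symbols; all scores 1 so nothing is filtered.
edges_of <- function(pairs) {
  data.frame(a = pairs[, 1], b = pairs[, 2], score = 1,
             stringsAsFactors = FALSE)
}

path_graph <- function(symbols) {
  n <- length(symbols)
  edges_of(cbind(symbols[-n], symbols[-1]))
}

complete_graph <- function(symbols) {
  edges_of(t(combn(symbols, 2)))
}

star_graph <- function(center, leaves) {
  edges_of(cbind(center, leaves))
}

# Random simple graph as an edge table, connected nodes only.
random_edge_table <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
  syms <- sprintf("N%02d", seq_len(n))
  edges_of(cbind(syms[pairs[keep, 1]], syms[pairs[keep, 2]]))
}

# Brute-force betweenness oracle: all-pairs hop distances from
# igraph::distances, shortest-path counts by dynamic programming over
# distance layers, then the pair-sum sigma_vt(s)/sigma_vt with
# sigma_vt(s) = sigma_vs * sigma_st whenever d(v,s) + d(s,t) = d(v,t).
brute_betweenness <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  # sigma[v, t]: number of shortest v-t paths
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]))
    for (t in reach[order(d[v, reach])]) {
      if (t == v) next
      pred <- which(adj[, t] & d[v, ] == d[v, t] - 1)
      sigma[v, t] <- sum(sigma[v, pred])
    }
  }
  betw <- numeric(n)
  for (s in seq_len(n)) {
    acc <- 0
    for (v in seq_len(n - 1)) {
      for (t in (v + 1):n) {
        if (v == s || t == s || is.infinite(d[v, t])) next
        if (is.finite(d[v, s]) && d[v, s] + d[s, t] == d[v, t]) {
          acc <- acc + sigma[v, s] * sigma[s, t] / sigma[v, t]
        }
      }
    }
    betw[s] <- acc
  }
  setNames(betw, igraph::V(g)$name)
}

# Exponential-closeness oracle straight from the distance matrix.
brute_exp_closeness <- function(net) {
  d <- igraph::distances(net$graph)
  diag(d) <- Inf
  rowSums(exp(-d))
}

# Exact hypergeometric upper tail by direct enumeration of choose()
# products; exact in double arithmetic for the N <= 25 cases it is used
# on.
enum_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
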