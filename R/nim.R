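# Node-importance (Nim) centrality.
#
# For node s,
#
#   Nim(s) = sqrt( B(s) * C(s) ),
#   B(s)   = sum over unordered pairs {v, t}, v != s != t, of
#            sigma_vt(s) / sigma_vt        (unnormalized betweenness),
#   C(s)   = sum over x != s of exp(-d(s, x))  (exponential closeness),
#
# with hop-count distances d, sigma_vt the number of shortest v-t paths and
# sigma_vt(s) those passing through s. Disconnected pairs contribute 0 to
# B, unreachable nodes contribute exp(-Inf) = 0 to C. Neither factor is
# normalized. The betweenness term is accumulated with Brandes'
# dependency recursion (one BFS per source, O(nm)); the same BFS sweeps
# supply the distances for the closeness term.

#' Compute the node-importance (Nim) centrality for every node
#'
#' @param net A non-empty `ppi_network`.
#' @return A `data.frame` with one row per node: `node`, `betweenness`
#'   (unnormalized, each unordered pair counted once), `exp_closeness`
#'   (sum of `exp(-d)` to all other nodes), `nim`
#'   (`sqrt(betweenness * exp_closeness)`) and `rank` (1-based dense rank
#'   by `nim` descending). Rows are ordered by rank, ties broken by higher
#'   betweenness then symbol.
#' @export
compute_nim <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  al <- adjacency_list(net)
  n <- length(al$names)
  if (n == 0L) stop_invalid("network is empty")

  betw <- numeric(n)
  expclo <- numeric(n)
  for (s in seq_len(n)) {
    b <- bfs_sigma(al$adj, n, s)
    reach <- is.finite(b$dist)
    reach[s] <- FALSE
    expclo[s] <- sum(exp(-b$dist[reach]))
    # Brandes back-propagation of pair dependencies
    delta <- numeric(n)
    for (w in rev(b$order)) {
      for (v in b$preds[[w]]) {
        delta[v] <- delta[v] + b$sigma[v] / b$sigma[w] * (1 + delta[w])
      }
      if (w != s) betw[w] <- betw[w] + delta[w]
    }
  }
  betw <- betw / 2 # each unordered pair was seen from both endpoints

  nim <- sqrt(betw * expclo)
  ord <- order(-nim, -betw, al$names)
  out <- data.frame(
    node = al$names[ord], betweenness = betw[ord],
    exp_closeness = expclo[ord], nim = nim[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
  # dense rank: equal nim shares a rank
  out$rank <- cumsum(!duplicated(signif(out$nim, 12)))
  out
}

#' Select hub nodes from a Nim table
#'
#' @param table Output of [compute_nim()].
#' @param rule `"top_k"` keeps the `k` highest-Nim nodes (ties broken by
#'   higher betweenness, then symbol); `"above_mean"` keeps nodes whose Nim
#'   strictly exceeds the arithmetic mean Nim over all nodes (zeros
#'   included).
#' @param k Number of hubs under `"top_k"` (default 30). If `k` exceeds the
#'   node count, all nodes are returned with a warning.
#' @return Character vector of hub symbols, sorted.
#' @export
select_hubs <- function(table, rule = c("top_k", "above_mean"), k = 30L) {
  rule <- match.arg(rule)
  if (nrow(table) == 0L) stop_invalid("Nim table is empty")
  if (rule == "above_mean") {
    return(sort(table$node[table$nim > mean(table$nim)]))
  }
  if (k < 1L) stop_invalid("`k` must be positive")
  if (k > nrow(table)) {
    warning("k = ", k, " exceeds the ", nrow(table),
            " network nodes; returning all", call. = FALSE)
    k <- nrow(table)
  }
  ord <- order(-table$nim, -table$betweenness, table$node)
  sort(table$node[ord][seq_len(k)])
}
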