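# PPI network construction and unweighted shortest-path machinery.
#
# The graph container is igraph (undirected, simple, edge attribute
# `score` in [0,1]); shortest paths are hop counts -- interaction scores
# act only as the confidence filter at construction time, never as path
# weights.

#' Construct a PPI network from a scored edge table
#'
#' @param edges A `data.frame` whose first three columns are node a, node b
#'   and a numeric score in `[0, 1]`. Self-loops are removed; parallel
#'   edges collapse to the maximum score.
#' @return A `ppi_network` object wrapping an undirected simple igraph.
#' @export
new_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L) stop_invalid("`edges` needs columns a, b, score")
  names(edges)[1:3] <- c("a", "b", "score")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  edges$score <- as.numeric(edges$score)
  edges <- edges[edges$a != edges$b & !is.na(edges$score), , drop = FALSE]
  if (any(edges$score < 0 | edges$score > 1)) {
    stop_invalid("edge scores must lie in [0, 1]")
  }
  # canonical unordered pair, collapse duplicates to the max score
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  key <- paste(lo, hi, sep = "\r")
  score <- tapply(edges$score, key, max)
  keys <- strsplit(names(score), "\r", fixed = TRUE)
  df <- data.frame(
    a = vapply(keys, `[`, "", 1L),
    b = vapply(keys, `[`, "", 2L),
    score = as.numeric(score), stringsAsFactors = FALSE
  )
  df <- df[order(df$a, df$b), , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::E(g)$score <- df$score
  structure(list(graph = g), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node names of a network
#' @param net A `ppi_network`.
#' @return Character vector of node symbols.
#' @export
network_nodes <- function(net) {
  igraph::V(net$graph)$name
}

#' Edge table of a network
#' @param net A `ppi_network`.
#' @return `data.frame` with columns `a`, `b`, `score`.
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  data.frame(a = el[, 1], b = el[, 2], score = igraph::E(net$graph)$score,
             stringsAsFactors = FALSE)
}

#' Build the high-confidence PPI network from STRING-style edge rows
#'
#' Edges are kept when their combined score is strictly above
#' `score_threshold`. Files using the 0-1000 integer score dialect are
#' detected (any score > 1) and rescaled by 1/1000 before comparison. If
#' `restrict_to` is given, both endpoints must belong to it. Nodes without
#' a surviving edge do not appear in the graph.
#'
#' @param edge_rows `data.frame` whose first three columns are the two
#'   endpoints and the combined score (either 0-1 or 0-1000 scale).
#'   Malformed rows (missing endpoint or unparseable score) are skipped
#'   with a warning.
#' @param score_threshold Confidence threshold on the 0-1 scale, default
#'   0.9.
#' @param restrict_to Optional character vector of admissible symbols.
#' @return A `ppi_network`.
#' @export
build_network <- function(edge_rows, score_threshold = 0.9,
                          restrict_to = NULL) {
  if (score_threshold < 0 || score_threshold > 1) {
    stop_invalid("`score_threshold` must lie in [0, 1]")
  }
  edges <- as.data.frame(edge_rows, stringsAsFactors = FALSE)
  if (ncol(edges) < 3L) stop_invalid("`edge_rows` needs 3 columns")
  names(edges)[1:3] <- c("a", "b", "score")
  edges$score <- suppressWarnings(as.numeric(edges$score))
  bad <- is.na(edges$score) | !nzchar(as.character(edges$a)) |
    !nzchar(as.character(edges$b)) | is.na(edges$a) | is.na(edges$b)
  if (any(bad)) {
    warning("skipped ", sum(bad), " malformed edge row(s)", call. = FALSE)
    edges <- edges[!bad, , drop = FALSE]
  }
  if (nrow(edges) && any(edges$score > 1)) {
    edges$score <- edges$score / 1000
    if (any(edges$score > 1)) {
      stop_invalid("edge scores exceed 1 even on the 0-1000 scale")
    }
  }
  keep <- edges$score > score_threshold
  if (!is.null(restrict_to)) {
    keep <- keep & edges$a %in% restrict_to & edges$b %in% restrict_to
  }
  edges <- edges[keep, , drop = FALSE]
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop_invalid("no edges survive the score threshold / restriction; ",
                 "empty network")
  }
  new_network(edges)
}

# Integer adjacency list (1-based) plus the node name vector; the
# representation the Brandes and BFS routines run on.
adjacency_list <- function(net) {
  g <- net$graph
  list(
    adj = lapply(igraph::as_adj_list(g, mode = "all"), as.integer),
    names = igraph::V(g)$name
  )
}

# Single-source BFS returning, in igraph vertex order: integer hop
# distances (NA_real_ -> Inf for unreachable), shortest-path counts sigma,
# the visit order, and each vertex's predecessor list on shortest paths.
bfs_sigma <- function(adj, n, s) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  order_visited <- integer(n)
  dist[s] <- 0
  sigma[s] <- 1
  queue <- integer(n)
  queue[1] <- s
  qhead <- 1L
  qtail <- 1L
  nvis <- 0L
  while (qhead <= qtail) {
    v <- queue[qhead]
    qhead <- qhead + 1L
    nvis <- nvis + 1L
    order_visited[nvis] <- v
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        qtail <- qtail + 1L
        queue[qtail] <- w
      }
      if (dist[w] == dist[v] + 1) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds,
       order = order_visited[seq_len(nvis)])
}

#' Unweighted shortest-path distances and path counts from one source
#'
#' Breadth-first search from `s`: hop-count distances and the number of
#' distinct shortest paths to every node. Unreachable nodes get distance
#' `Inf` and path count 0.
#'
#' @param net A `ppi_network`.
#' @param s Source node symbol; must be in the network.
#' @return A list with named numeric vectors `dist` and `sigma` over all
#'   nodes.
#' @export
shortest_paths_from <- function(net, s) {
  al <- adjacency_list(net)
  i <- match(s, al$names)
  if (is.na(i)) stop_invalid("node `", s, "` is not in the network")
  b <- bfs_sigma(al$adj, length(al$names), i)
  list(dist = setNames(b$dist, al$names),
       sigma = setNames(b$sigma, al$names))
}
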