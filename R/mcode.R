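# MCODE-style dense module detection, reconstructed from the published
# algorithm: vertex weighting by the core-clustering coefficient of the
# closed neighborhood, greedy seeded growth with a weight-percentage
# admission threshold, then haircut / optional fluff post-processing.

#' MCODE parameters
#'
#' Defaults are the plugin's documented defaults.
#'
#' @param degree_cutoff Minimum degree for a vertex to receive a nonzero
#'   weight (default 2).
#' @param node_score_cutoff Admission slack in `[0, 1]` (default 0.2): a
#'   neighbor joins a module when its weight is at least
#'   `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core Minimum core level for the neighborhood core to count
#'   (default 2); neighborhoods whose highest core is below it score 0.
#' @param max_depth Maximum growth depth from the seed (default 100).
#' @param haircut Remove singly-connected module members, iterated to a
#'   fixed point (default `TRUE`).
#' @param fluff Add boundary vertices whose neighborhood density exceeds
#'   `fluff_density` (default `FALSE`); fluffed vertices may be shared
#'   between modules.
#' @param fluff_density Density threshold for fluff (default 0.1).
#' @return A `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.1) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1) {
    stop_invalid("`node_score_cutoff` must lie in [0, 1]")
  }
  structure(
    list(degree_cutoff = as.integer(degree_cutoff),
         node_score_cutoff = node_score_cutoff,
         k_core = as.integer(k_core), max_depth = as.integer(max_depth),
         haircut = isTRUE(haircut), fluff = isTRUE(fluff),
         fluff_density = fluff_density),
    class = "mcode_params"
  )
}

# density of an igraph (0 for < 2 vertices)
graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weight
#'
#' Weight of `v` is `k_max * density(core)`, where `core` is the highest
#' k-core of the closed neighborhood of `v` and `density = 2E / (N(N-1))`
#' of that core. Vertices with degree below `degree_cutoff`, or whose
#' neighborhood's highest core is below `k_core`, weigh 0.
#'
#' @param net A `ppi_network`.
#' @param v Node symbol.
#' @param degree_cutoff Minimum degree (default 2).
#' @param k_core Minimum admissible core level (default 2).
#' @return Non-negative numeric weight.
#' @export
vertex_weight <- function(net, v, degree_cutoff = 2L, k_core = 2L) {
  g <- net$graph
  i <- match(v, igraph::V(g)$name)
  if (is.na(i)) stop_invalid("node `", v, "` is not in the network")
  if (igraph::degree(g, i) < degree_cutoff) return(0)
  nb <- igraph::induced_subgraph(
    g, c(i, as.integer(igraph::neighbors(g, i)))
  )
  core <- igraph::coreness(nb)
  k_max <- max(core)
  if (k_max < k_core) return(0)
  core_sub <- igraph::induced_subgraph(nb, which(core >= k_max))
  k_max * graph_density(core_sub)
}

# weights for all vertices at once
mcode_weights <- function(net, params) {
  nodes <- network_nodes(net)
  vapply(nodes, function(v) {
    vertex_weight(net, v, params$degree_cutoff, params$k_core)
  }, numeric(1))
}

# Greedy breadth-limited growth from `seed` (an index): admit unassigned
# neighbors whose weight >= w[seed] * (1 - cutoff). Returns member indices.
mcode_grow <- function(adj, w, seed, assigned, cutoff, max_depth) {
  threshold <- w[seed] * (1 - cutoff)
  members <- seed
  in_module <- logical(length(w))
  in_module[seed] <- TRUE
  frontier <- seed
  depth <- 0L
  while (length(frontier) && depth < max_depth) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (!in_module[u] && !assigned[u] && w[u] >= threshold) {
          in_module[u] <- TRUE
          nxt <- c(nxt, u)
        }
      }
    }
    members <- c(members, nxt)
    frontier <- nxt
    depth <- depth + 1L
  }
  members
}

#' Detect dense modules (MCODE-style)
#'
#' Vertices are weighted by [vertex_weight()]; modules grow greedily from
#' the highest-weight unassigned seed (ties broken by degree, then
#' symbol), admitting neighbors whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)` up to `max_depth` levels. Each
#' vertex belongs to at most one module. Haircut then strips members with
#' fewer than two in-module neighbors (to a fixed point); optional fluff
#' adds boundary vertices with dense neighborhoods. Modules with fewer
#' than 3 members are discarded. The module score is
#' `density * member count` of the induced subgraph.
#'
#' @param net A non-empty `ppi_network`.
#' @param params An [mcode_params()] object.
#' @return A list of `dense_module` objects ordered by score descending
#'   (ties by seed symbol), each a list with `members` (sorted symbols),
#'   `score`, `seed_node`.
#' @export
find_modules <- function(net, params = mcode_params()) {
  stopifnot(inherits(net, "ppi_network"))
  g <- net$graph
  al <- adjacency_list(net)
  n <- length(al$names)
  if (n == 0L) stop_invalid("network is empty")
  w <- unname(mcode_weights(net, params))
  deg <- igraph::degree(g)

  seed_order <- order(-w, -deg, al$names)
  assigned <- logical(n)
  modules <- list()
  for (seed in seed_order) {
    if (assigned[seed] || w[seed] <= 0) next
    members <- mcode_grow(al$adj, w, seed, assigned, params$node_score_cutoff,
                          params$max_depth)
    assigned[members] <- TRUE
    if (params$haircut) {
      repeat {
        sub <- igraph::induced_subgraph(g, members)
        low <- igraph::degree(sub) < 2
        if (!any(low)) break
        members <- members[!low]
        if (length(members) == 0L) break
      }
    }
    if (params$fluff && length(members)) {
      boundary <- setdiff(unique(unlist(al$adj[members])), members)
      fluffed <- boundary[vapply(boundary, function(v) {
        nb <- igraph::induced_subgraph(
          g, c(v, as.integer(igraph::neighbors(g, v)))
        )
        graph_density(nb) > params$fluff_density
      }, logical(1))]
      members <- c(members, fluffed) # fluffed nodes stay shareable
    }
    if (length(members) < 3L) next
    sub <- igraph::induced_subgraph(g, members)
    modules[[length(modules) + 1L]] <- structure(
      list(members = sort(al$names[members]),
           score = graph_density(sub) * length(members),
           seed_node = al$names[seed]),
      class = "dense_module"
    )
  }
  ord <- order(-vapply(modules, `[[`, numeric(1), "score"),
               vapply(modules, `[[`, character(1), "seed_node"))
  modules[ord]
}

#' @export
print.dense_module <- function(x, ...) {
  cat(sprintf("dense_module (seed %s, score %.3f, %d members): %s\n",
              x$seed_node, x$score, length(x$members),
              paste(x$members, collapse = ", ")))
  invisible(x)
}
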