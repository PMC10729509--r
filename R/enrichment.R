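# Over-representation analysis against a GMT-backed gene-set collection.
#
# The test is the one-sided hypergeometric upper tail P[X >= k] for an
# overlap of k between the query (size n in the universe) and a set of
# size K out of a universe of N annotated symbols; q-values are
# Benjamini-Hochberg adjusted p-values, and the screening rule is the dual
# threshold p < p_cut AND q < q_cut.

#' Gene-set collection
#'
#' @param sets Named list of character vectors (set id -> member symbols).
#' @param description Optional named character vector of set descriptions.
#' @param universe Optional character vector of annotated symbols; defaults
#'   to the union of all set members. Members must all belong to it.
#' @return A `geneset_collection` object.
#' @export
geneset_collection <- function(sets, description = NULL, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop_invalid("`sets` must be a uniquely named list")
  }
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  members <- unique(unlist(sets, use.names = FALSE))
  if (is.null(universe)) {
    universe <- members
  } else if (!all(members %in% universe)) {
    stop_invalid("all set members must belong to the universe")
  }
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  }
  structure(
    list(sets = sets, description = description,
         universe = sort(unique(as.character(universe)))),
    class = "geneset_collection"
  )
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets over %d symbols\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric upper-tail probability P[X >= k]
#'
#' Probability of observing an overlap of at least `k` between a query of
#' size `n` and a set of size `K`, drawn from a universe of size `N`.
#' Computed in log space via the stable distribution-function routine, so
#' tiny tails do not underflow to 0 prematurely.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Set size.
#' @param n Query size.
#' @param N Universe size.
#' @return Probability in (0, 1]; exactly 1 when `k == 0`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n))) {
    stop_invalid("inconsistent counts: need 0 <= k <= min(K, n), K,n <= N")
  }
  # P[X >= k] = 1 - P[X <= k-1]
  ifelse(k == 0, 1,
         phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a query gene set
#'
#' Query symbols outside the collection's universe are dropped (with a
#' note); each set overlapping the query in at least one gene is tested
#' with [hypergeom_tail()]; q-values are BH-adjusted over the tested sets.
#' A set passes when `p_value < p_cut` and `q_value < q_cut` (strict).
#'
#' @param query Character vector of query symbols.
#' @param collection A [geneset_collection()].
#' @param p_cut,q_cut Screening thresholds (defaults 0.05 / 0.05).
#' @return `data.frame` sorted by `p_value` ascending (ties by set id):
#'   `set_id`, `k` (overlap), `K` (set size), `n` (effective query size),
#'   `N` (universe size), `p_value`, `p_adjusted`, `q_value`, `passes`.
#' @export
enrich <- function(query, collection, p_cut = 0.05, q_cut = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  query <- unique(as.character(query))
  eff <- intersect(query, collection$universe)
  dropped <- length(query) - length(eff)
  if (dropped > 0L) {
    message(dropped, " query symbol(s) outside the annotation universe ",
            "dropped")
  }
  if (length(eff) == 0L) {
    stop_invalid("query does not intersect the annotation universe")
  }
  N <- length(collection$universe)
  n <- length(eff)
  k <- vapply(collection$sets, function(s) length(intersect(s, eff)),
              integer(1))
  K <- lengths(collection$sets)
  testable <- k >= 1L
  out <- data.frame(
    set_id = names(collection$sets)[testable], k = k[testable],
    K = unname(K[testable]), n = n, N = N, stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$p_value <- hypergeom_tail(out$k, out$K, out$n, out$N)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$q_value <- out$p_adjusted
  out$passes <- out$p_value < p_cut & out$q_value < q_cut
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Members of a set restricted to a gene universe of interest
#'
#' @param collection A [geneset_collection()].
#' @param set_id Set identifier; must exist in the collection.
#' @param restrict Character vector to intersect the members with.
#' @return Sorted character vector of `members(set_id)` intersected with
#'   `restrict`.
#' @export
genes_in_set <- function(collection, set_id, restrict) {
  stopifnot(inherits(collection, "geneset_collection"))
  if (!set_id %in% names(collection$sets)) {
    stop_invalid("unknown set id `", set_id, "`")
  }
  sort(intersect(collection$sets[[set_id]], restrict))
}
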