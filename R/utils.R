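#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt phyper p.adjust rnorm runif var sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Synthesized gene symbols: "G0001", "G0002", ... Zero-padding keeps
# lexicographic and numeric order identical, which tie-breaking relies on.
gene_symbols <- function(n) {
  width <- max(4L, nchar(as.character(n)))
  sprintf(paste0("G%0", width, "d"), seq_len(n))
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Scoped RNG: run `expr` under `seed` without disturbing the caller's RNG
# stream, so generators are pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Canonicalize gene symbols against an offline synonym table
#'
#' Symbols are upper-cased and then mapped through the alias table. The
#' mapping is idempotent: canonical symbols map to themselves, and symbols
#' absent from the table pass through unchanged (upper-cased).
#'
#' @param symbols Character vector of gene symbols or aliases.
#' @param universe A gene universe created by [gene_universe()], or `NULL`
#'   for plain upper-casing.
#' @return Character vector of canonical symbols, same length as `symbols`.
#' @export
canonicalize_symbols <- function(symbols, universe = NULL) {
  out <- toupper(trimws(as.character(symbols)))
  if (!is.null(universe)) {
    hit <- match(out, names(universe$canonical))
    mapped <- !is.na(hit)
    out[mapped] <- unname(universe$canonical[hit[mapped]])
  }
  out
}

#' Build a gene universe from an alias-to-canonical synonym table
#'
#' @param alias Character vector of alias symbols.
#' @param canonical Character vector of canonical symbols, parallel to
#'   `alias`.
#' @return A `gene_universe` object: a named canonical map (alias ->
#'   canonical, upper-cased, canonical symbols self-mapped) and the member
#'   set of canonical symbols.
#' @export
gene_universe <- function(alias = character(), canonical = character()) {
  if (length(alias) != length(canonical)) {
    stop_invalid("`alias` and `canonical` must have equal length")
  }
  alias <- toupper(trimws(alias))
  canonical <- toupper(trimws(canonical))
  map <- setNames(canonical, alias)
  # canonical symbols map to themselves (idempotence)
  self <- setdiff(canonical, names(map))
  map <- c(map, setNames(self, self))
  structure(
    list(canonical = map, members = sort(unique(canonical))),
    class = "gene_universe"
  )
}
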