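# Disease-gene assembly from scored database snapshots.
#
# Each source table carries its own filter rule (evidence tags for CTD,
# strict score thresholds for DisGeNET and GeneCards, a present Entrez id
# for OMIM, keep-all for PharmGKB/TTD/custom); the filtered sets are
# unioned with the differential-expression hits, after canonicalization
# through an offline synonym table, into the disease gene set.

.source_names <- c("CTD", "DisGeNET", "GeneCards", "OMIM", "PharmGKB",
                   "TTD", "custom")

.ctd_keep <- c("marker/mechanism", "marker/mechanism|therapeutic",
               "therapeutic")

#' Disease-gene source table
#'
#' @param source_name One of `"CTD"`, `"DisGeNET"`, `"GeneCards"`,
#'   `"OMIM"`, `"PharmGKB"`, `"TTD"`, `"custom"`; determines the filter
#'   rule [filter_source()] applies.
#' @param records A `data.frame` with column `symbol` and optional columns
#'   `score` (numeric), `evidence` (character), `entrez_id` (character);
#'   must be non-empty.
#' @return A `source_table` object.
#' @export
source_table <- function(source_name, records) {
  source_name <- match.arg(source_name, .source_names)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) stop_invalid("`records` must be non-empty")
  if (!"symbol" %in% names(records)) {
    stop_invalid("`records` must have a `symbol` column")
  }
  for (col in c("score", "evidence", "entrez_id")) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col == "score") NA_real_ else NA_character_
    }
  }
  records$score <- as.numeric(records$score)
  structure(list(source_name = source_name, records = records),
            class = "source_table")
}

#' Filter a source table by its database-specific rule
#'
#' Rules: CTD keeps records whose direct-evidence tag is
#' `marker/mechanism`, `marker/mechanism|therapeutic` (spaces around the
#' pipe are ignored) or `therapeutic`; DisGeNET keeps gene-disease scores
#' strictly above 0.1; GeneCards keeps relevance scores strictly above 5;
#' OMIM keeps records with a non-empty Entrez id; PharmGKB, TTD and custom
#' keep everything. DisGeNET/GeneCards records with a missing score are
#' dropped with a warning.
#'
#' @param table A [source_table()].
#' @return Character vector of (uppercased) surviving symbols, sorted and
#'   deduplicated.
#' @export
filter_source <- function(table) {
  stopifnot(inherits(table, "source_table"))
  rec <- table$records
  keep <- switch(
    table$source_name,
    CTD = {
      ev <- gsub("[[:space:]]", "", tolower(rec$evidence))
      ev %in% tolower(.ctd_keep)
    },
    DisGeNET = ,
    GeneCards = {
      cut <- if (table$source_name == "DisGeNET") 0.1 else 5
      missing_score <- is.na(rec$score)
      if (any(missing_score)) {
        warning(sprintf("%s: dropped %d record(s) with missing score",
                        table$source_name, sum(missing_score)),
                call. = FALSE)
      }
      !missing_score & rec$score > cut
    },
    OMIM = !is.na(rec$entrez_id) & nzchar(trimws(rec$entrez_id)),
    rep(TRUE, nrow(rec)) # PharmGKB, TTD, custom
  )
  sort(unique(toupper(trimws(rec$symbol[keep]))))
}

#' Assemble the disease gene set
#'
#' Unions the differential-expression hits with the filtered symbols from
#' every source, canonicalizing each symbol through the universe's synonym
#' table so aliases collapse to a single entry. Symbols absent from the
#' synonym table pass through (uppercased) with a note.
#'
#' @param deg_genes Character vector of DEG symbols.
#' @param sources List of [source_table()] objects.
#' @param universe Optional [gene_universe()] for canonicalization.
#' @return Sorted character vector of canonical disease-gene symbols.
#' @export
assemble_disease_set <- function(deg_genes, sources = list(),
                                 universe = NULL) {
  from_sources <- unlist(lapply(sources, filter_source), use.names = FALSE)
  all_symbols <- c(as.character(deg_genes), from_sources)
  canon <- canonicalize_symbols(all_symbols, universe)
  if (!is.null(universe)) {
    unknown <- unique(canon[!canon %in% names(universe$canonical)])
    if (length(unknown)) {
      message(length(unknown),
              " symbol(s) not in the synonym table passed through unchanged")
    }
  }
  out <- sort(unique(canon))
  if (length(out) == 0L) {
    stop_invalid("disease gene set is empty: no DEGs and no source genes")
  }
  out
}
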