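# Flat-file readers and writers: expression TSV + group sidecar,
# STRING-style edge lists, per-source disease tables, synonym tables, GMT
# collections, and the truth/report JSON. Everything is plain text.

#' Write / read an expression matrix as TSV plus a group-label sidecar
#'
#' The matrix file has gene ids in the first column (`gene`) and one
#' column per sample; the sidecar has columns `sample`, `group`.
#'
#' @param matrix An [expr_matrix()].
#' @param path Matrix TSV path.
#' @param groups_path Sidecar TSV path (default `<path>` with a
#'   `.groups.tsv` suffix).
#' @return Invisibly, the matrix path.
#' @export
write_expression_tsv <- function(matrix, path,
                                 groups_path = paste0(path, ".groups.tsv")) {
  df <- data.frame(gene = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gr <- data.frame(sample = colnames(matrix$values),
                   group = as.character(matrix$groups))
  write.table(gr, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path,
                                groups_path = paste0(path, ".groups.tsv")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  gr <- read.delim(groups_path, stringsAsFactors = FALSE)
  groups <- gr$group[match(colnames(values), gr$sample)]
  if (anyNA(groups)) stop_invalid("samples missing from the group sidecar")
  expr_matrix(values, factor(groups, levels = unique(gr$group)))
}

#' Write / read a STRING-style scored edge list
#'
#' Tab- or space-separated with header `protein1 protein2 combined_score`.
#'
#' @param edges `data.frame` with three columns (endpoints, score).
#' @param path File path.
#' @return Invisibly the path; the reader returns the edge `data.frame`.
#' @export
write_edges_tsv <- function(edges, path) {
  edges <- as.data.frame(edges)[, 1:3]
  names(edges) <- c("protein1", "protein2", "combined_score")
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("protein|node|score", first, ignore.case = TRUE)
  df <- read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_invalid("edge file needs 3 columns")
  names(df)[1:3] <- c("protein1", "protein2", "combined_score")
  df[, 1:3]
}

#' Read a per-source disease-gene table
#'
#' TSV with a `symbol` column and optional `score`, `evidence`,
#' `entrez_id` columns.
#'
#' @param path File path.
#' @param source_name The source whose filter rule applies (see
#'   [source_table()]).
#' @return A [source_table()].
#' @export
read_source_tsv <- function(path, source_name) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  source_table(source_name, df)
}

#' Read an alias-to-canonical synonym table
#'
#' Two-column TSV (`alias`, `canonical`).
#'
#' @param path File path.
#' @return A [gene_universe()].
#' @export
read_synonyms_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  gene_universe(df[[1]], df[[2]])
}

#' Write / read a gene-set collection in GMT format
#'
#' One set per line: id, description, then member symbols, tab-separated.
#'
#' @param collection A [geneset_collection()].
#' @param path File path.
#' @return Invisibly the path; the reader returns a
#'   [geneset_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$description[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  desc <- setNames(vapply(parts, `[`, "", 2L), ids)
  sets <- setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  geneset_collection(sets, desc)
}

#' Write planted truth or a prioritization report as JSON
#'
#' @param x A [synthetic_truth()] or `prioritization_report`.
#' @param path File path.
#' @return Invisibly the path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Read an expression block from a GEO series-matrix file
#'
#' Extracts the tab-separated table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#'
#' @param path Path to a series-matrix text file.
#' @return Numeric matrix with probe/gene ids as rownames and sample
#'   accessions as colnames.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop_invalid("no series-matrix table block found")
  }
  block <- lines[(begin + 1L):(end - 1L)]
  df <- read.delim(text = block, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- gsub('"', "", df[[1]])
  values
}
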