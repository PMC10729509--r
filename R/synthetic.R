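# Synthetic-data generators.
#
# Every pipeline input -- a two-group expression matrix, per-source
# disease-gene tables, a scored PPI edge list, and a gene-set collection --
# can be generated with known planted truth, so each downstream stage is
# testable without any external download. All generators are pure functions
# of their arguments: the same seed reproduces identical output bit-for-bit
# and the caller's RNG stream is left untouched.

#' Planted ground truth of a synthetic dataset
#'
#' @param de_genes Symbols planted as differentially expressed.
#' @param clique_genes Symbols forming the planted dense module.
#' @param enriched_set_id Identifier of the planted over-represented set.
#' @param target_genes Symbols planted to satisfy all three prioritization
#'   criteria simultaneously (`target_genes` is contained in both
#'   `clique_genes` and the planted set's members).
#' @param seed Integer seed the dataset was generated from.
#' @return A `synthetic_truth` object (a list with the five fields above).
#' @export
synthetic_truth <- function(de_genes = character(), clique_genes = character(),
                            enriched_set_id = NA_character_,
                            target_genes = character(), seed = NA_integer_) {
  structure(
    list(
      de_genes = sort(unique(de_genes)),
      clique_genes = sort(unique(clique_genes)),
      enriched_set_id = enriched_set_id,
      target_genes = sort(unique(target_genes)),
      seed = seed
    ),
    class = "synthetic_truth"
  )
}

#' Simulate a two-group log2 expression matrix with planted effects
#'
#' Emulates a case/control microarray design: per-gene baseline levels are
#' drawn once, group means differ by `effect_log2fc` for exactly `n_de`
#' planted genes (half shifted up in cases, half down, odd remainder up),
#' and every value is the group mean plus i.i.d. Gaussian noise.
#'
#' Planted genes are the first `n_de` symbols of the universe; this
#' deterministic placement lets the other generators plant their structures
#' inside the differentially expressed set.
#'
#' @param n_genes Number of genes (rows).
#' @param n_per_group Samples per group (columns are `2 * n_per_group`).
#' @param n_de Number of planted differentially expressed genes.
#' @param effect_log2fc Planted absolute group-mean difference (log2 scale).
#' @param noise_sd Standard deviation of the Gaussian noise, must be > 0.
#' @param seed Integer random seed.
#' @return A list with `matrix` (an [expr_matrix()]) and `truth` (a
#'   [synthetic_truth()] with `de_genes` filled in).
#' @export
simulate_expression <- function(n_genes, n_per_group, n_de,
                                effect_log2fc = 2, noise_sd = 1, seed = 1L) {
  if (n_genes < 1L) stop_invalid("`n_genes` must be positive")
  if (n_per_group < 2L) stop_invalid("`n_per_group` must be at least 2")
  if (n_de < 0L || n_de > n_genes) {
    stop_invalid("`n_de` must lie in [0, n_genes]")
  }
  if (effect_log2fc <= 0) stop_invalid("`effect_log2fc` must be positive")
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be positive")

  genes <- gene_symbols(n_genes)
  n_samp <- 2L * n_per_group
  groups <- factor(rep(c("control", "case"), each = n_per_group),
                   levels = c("control", "case"))
  samples <- c(sprintf("CTRL%02d", seq_len(n_per_group)),
               sprintf("CASE%02d", seq_len(n_per_group)))

  with_seed(seed, {
    base <- runif(n_genes, min = 4, max = 10)
    shift <- numeric(n_genes)
    if (n_de > 0L) {
      n_up <- ceiling(n_de / 2)
      shift[seq_len(n_de)] <- rep(c(1, -1), c(n_up, n_de - n_up)) *
        effect_log2fc
    }
    mu <- outer(base, rep(0, n_samp), "+")
    mu[, groups == "case"] <- mu[, groups == "case"] + shift
    values <- mu + matrix(rnorm(n_genes * n_samp, sd = noise_sd),
                          n_genes, n_samp)
    dimnames(values) <- list(genes, samples)
    list(
      matrix = expr_matrix(values, groups),
      truth = synthetic_truth(de_genes = genes[seq_len(n_de)], seed = seed)
    )
  })
}

#' Simulate a scored PPI edge list with a planted dense clique
#'
#' The background is an Erdős–Rényi graph G(`n_background`, `p_edge`);
#' on top of it, the first `clique_size` symbols are made pairwise adjacent.
#' Planted-clique edges receive combined scores uniform in (0.9, 1], so they
#' all survive the conventional high-confidence score filter; background
#' edges receive scores uniform in (0, 1], so only about 10% do.
#'
#' @param n_background Number of nodes.
#' @param p_edge Background edge probability, in (0, 1).
#' @param clique_size Size of the planted clique (>= 3).
#' @param seed Integer random seed.
#' @return A list with `network` (an unthresholded [new_network()] over the
#'   generated edges), `edges` (the raw scored edge table, columns
#'   `protein1`, `protein2`, `combined_score`) and `truth`.
#' @export
simulate_ppi <- function(n_background, p_edge, clique_size, seed = 1L) {
  if (p_edge <= 0 || p_edge >= 1) stop_invalid("`p_edge` must lie in (0, 1)")
  if (clique_size < 3L) stop_invalid("`clique_size` must be at least 3")
  if (clique_size > n_background) {
    stop_invalid("`clique_size` cannot exceed `n_background`")
  }

  nodes <- gene_symbols(n_background)
  clique <- nodes[seq_len(clique_size)]

  pairs <- t(utils::combn(n_background, 2L))
  in_clique <- pairs[, 1] <= clique_size & pairs[, 2] <= clique_size

  with_seed(seed, {
    keep_bg <- runif(nrow(pairs)) < p_edge
    keep <- in_clique | keep_bg
    a <- nodes[pairs[keep, 1]]
    b <- nodes[pairs[keep, 2]]
    cl <- in_clique[keep]
    score <- numeric(length(a))
    score[cl] <- 0.9 + runif(sum(cl)) * 0.1
    score[!cl] <- runif(sum(!cl))
    edges <- data.frame(protein1 = a, protein2 = b, combined_score = score,
                        stringsAsFactors = FALSE)
    list(
      network = new_network(edges),
      edges = edges,
      truth = synthetic_truth(clique_genes = clique, seed = seed)
    )
  })
}

#' Simulate a gene-set collection with one planted over-represented set
#'
#' One set (the first, id ending in `_PLANTED`) contains all
#' `planted_members` plus random fill from the universe; the remaining sets
#' are drawn uniformly from the universe with sizes uniform in
#' `set_size_range`.
#'
#' @param universe Character vector of symbols the sets draw from.
#' @param n_sets Number of sets in the collection.
#' @param set_size_range Length-2 integer vector, inclusive size range.
#' @param planted_members Symbols guaranteed to be in the planted set; must
#'   all belong to `universe`. May be empty (pure null collection).
#' @param seed Integer random seed.
#' @return A list with `collection` (a [geneset_collection()]) and `truth`
#'   (with `enriched_set_id` filled in).
#' @export
simulate_genesets <- function(universe, n_sets, set_size_range = c(10L, 25L),
                              planted_members = character(), seed = 1L) {
  universe <- unique(as.character(universe))
  if (n_sets < 1L) stop_invalid("`n_sets` must be positive")
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2]) {
    stop_invalid("`set_size_range` must be an increasing length-2 range")
  }
  if (!all(planted_members %in% universe)) {
    stop_invalid("`planted_members` must all belong to `universe`")
  }

  ids <- sprintf("PW%04d", seq_len(n_sets))
  ids[1] <- paste0(ids[1], "_PLANTED")

  with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]),
                    n_sets, replace = TRUE)
    sizes[1] <- max(sizes[1], length(planted_members))
    sets <- vector("list", n_sets)
    fill_pool <- setdiff(universe, planted_members)
    n_fill <- sizes[1] - length(planted_members)
    sets[[1]] <- sort(c(planted_members,
                        sample(fill_pool, min(n_fill, length(fill_pool)))))
    for (i in seq_len(n_sets)[-1]) {
      sets[[i]] <- sort(sample(universe, min(sizes[i], length(universe))))
    }
    names(sets) <- ids
    desc <- setNames(sprintf("synthetic gene set %d", seq_len(n_sets)), ids)
    desc[1] <- "synthetic planted over-represented set"
    list(
      collection = geneset_collection(sets, desc),
      truth = synthetic_truth(enriched_set_id = ids[1], seed = seed)
    )
  })
}

#' Simulate per-source disease-gene tables
#'
#' Emulates score/evidence-filtered database snapshots (CTD-style evidence
#' tags, DisGeNET/GeneCards-style scores, OMIM entrez ids, keep-all
#' sources). Each table mixes `disease_genes` carrying passing scores or
#' evidence with random decoy genes carrying failing ones, so
#' [filter_source()] recovers (a subset of) the disease genes and nothing
#' else.
#'
#' @param universe Symbols to draw decoys from.
#' @param disease_genes Symbols the sources should report as disease-linked.
#' @param sources Character vector of source names to simulate.
#' @param n_hits_per_source Number of disease genes reported per source.
#' @param n_decoys_per_source Number of failing decoy records per source.
#' @param seed Integer random seed.
#' @return Named list of [source_table()] objects.
#' @export
simulate_sources <- function(universe, disease_genes,
                             sources = c("CTD", "DisGeNET", "GeneCards",
                                         "OMIM", "PharmGKB", "TTD"),
                             n_hits_per_source = 5L,
                             n_decoys_per_source = 5L, seed = 1L) {
  universe <- unique(as.character(universe))
  disease_genes <- unique(as.character(disease_genes))
  decoy_pool <- setdiff(universe, disease_genes)

  with_seed(seed, {
    out <- lapply(sources, function(src) {
      hits <- sample(disease_genes,
                     min(n_hits_per_source, length(disease_genes)))
      decoys <- sample(decoy_pool,
                       min(n_decoys_per_source, length(decoy_pool)))
      n_h <- length(hits)
      n_d <- length(decoys)
      rec <- data.frame(
        symbol = c(hits, decoys),
        score = NA_real_, evidence = NA_character_,
        entrez_id = NA_character_, stringsAsFactors = FALSE
      )
      if (src == "CTD") {
        rec$evidence <- c(
          sample(c("marker/mechanism", "therapeutic",
                   "marker/mechanism|therapeutic"), n_h, replace = TRUE),
          rep("inferred", n_d)
        )
      } else if (src == "DisGeNET") {
        rec$score <- c(0.1 + runif(n_h) * 0.9, runif(n_d) * 0.1)
      } else if (src == "GeneCards") {
        rec$score <- c(5 + runif(n_h) * 20, runif(n_d) * 5)
      } else if (src == "OMIM") {
        rec$entrez_id <- c(as.character(sample.int(99999L, n_h)),
                           rep("", n_d))
      } else {
        # keep-all sources report hits only
        rec <- rec[seq_len(n_h), , drop = FALSE]
      }
      source_table(src, rec)
    })
    names(out) <- sources
    out
  })
}
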