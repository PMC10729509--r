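# End-to-end orchestration: differential expression -> disease-set
# assembly -> high-confidence PPI network -> Nim centrality + dense-module
# detection -> over-representation analysis -> triple intersection.

#' Triple intersection of module, hub and pathway genes
#'
#' The final prioritization step: a gene is nominated as a target when it
#' simultaneously (1) belongs to the selected dense module, (2) ranks
#' among the Nim hubs, and (3) sits in the chosen pathway. An empty
#' intersection is a valid result.
#'
#' @param module_genes Symbols of the selected dense module.
#' @param nim_top Symbols of the Nim hub set.
#' @param pathway_genes Symbols of the chosen pathway (restricted to the
#'   network).
#' @return A `prioritization_report`: the three input sets, their
#'   `intersection`, and a `provenance` data.frame (one row per gene in
#'   the union, logical columns `in_module`, `in_nim_top`, `in_pathway`,
#'   `in_intersection`).
#' @export
prioritize <- function(module_genes, nim_top, pathway_genes) {
  module_genes <- sort(unique(as.character(module_genes)))
  nim_top <- sort(unique(as.character(nim_top)))
  pathway_genes <- sort(unique(as.character(pathway_genes)))
  inter <- intersect(intersect(module_genes, nim_top), pathway_genes)
  all_genes <- sort(unique(c(module_genes, nim_top, pathway_genes)))
  prov <- data.frame(
    gene = all_genes,
    in_module = all_genes %in% module_genes,
    in_nim_top = all_genes %in% nim_top,
    in_pathway = all_genes %in% pathway_genes,
    stringsAsFactors = FALSE
  )
  prov$in_intersection <- prov$in_module & prov$in_nim_top & prov$in_pathway
  structure(
    list(module_genes = module_genes, nim_top = nim_top,
         pathway_genes = pathway_genes, intersection = sort(inter),
         provenance = prov, config_echo = NULL, log = character()),
    class = "prioritization_report"
  )
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat(sprintf(paste0(
    "prioritization_report\n",
    "  module genes : %d\n  nim hubs     : %d\n  pathway genes: %d\n",
    "  intersection : %s\n"),
    length(x$module_genes), length(x$nim_top), length(x$pathway_genes),
    if (length(x$intersection)) paste(x$intersection, collapse = ", ")
    else "(empty)"))
  invisible(x)
}

#' Configuration for a fully synthetic pipeline run
#'
#' Defaults describe a strong-planting recovery experiment: a clear
#' expression effect at microarray-like group sizes, a clique planted
#' inside the differentially expressed genes, and an over-represented set
#' planted inside the clique, so the planted targets survive every stage.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param n_genes Universe size (default 300).
#' @param n_per_group Samples per group (default 32, a typical two-arm
#'   microarray cohort).
#' @param n_de Planted DE genes (default 40).
#' @param effect_log2fc Planted log2 fold change (default 3).
#' @param noise_sd Expression noise SD (default 0.5).
#' @param p_edge Background PPI edge probability (default 0.05).
#' @param clique_size Planted clique size (default 12); must not exceed
#'   `n_de` so the clique survives the DEG screen.
#' @param n_overlap Planted members of the enriched set drawn from the
#'   clique (default 5); must not exceed `clique_size`.
#' @param n_source_extra Disease genes known to the database sources but
#'   not planted in the expression data (default 20), so the assembled
#'   set is a genuine union of the two evidence streams.
#' @param n_sets Gene sets in the collection (default 30).
#' @param set_size_range Set size range (default `c(10, 25)`).
#' @param score_threshold PPI confidence threshold (default 0.9).
#' @param deg_method `"moderated"` or `"welch"`.
#' @param fc_threshold,p_threshold DEG screen thresholds (1.0 / 0.05).
#' @param hub_rule `"top_k"` or `"above_mean"`.
#' @param hub_k Hub count under `top_k` (default 30).
#' @param pathway Set id for the third criterion; `NULL` means the
#'   planted set (the synthetic stand-in for the analyst's pathway
#'   choice).
#' @param mcode An [mcode_params()] object.
#' @return A `pipeline_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 300L, n_per_group = 32L,
                             n_de = 40L, effect_log2fc = 3, noise_sd = 0.5,
                             p_edge = 0.05, clique_size = 12L,
                             n_overlap = 5L, n_source_extra = 20L,
                             n_sets = 30L,
                             set_size_range = c(10L, 25L),
                             score_threshold = 0.9,
                             deg_method = "moderated", fc_threshold = 1.0,
                             p_threshold = 0.05, hub_rule = "top_k",
                             hub_k = 30L, pathway = NULL,
                             mcode = mcode_params()) {
  if (clique_size > n_de) {
    stop_invalid("`clique_size` must not exceed `n_de` ",
                 "(the clique is planted inside the DE genes)")
  }
  if (n_overlap > clique_size) {
    stop_invalid("`n_overlap` must not exceed `clique_size`")
  }
  structure(
    list(mode = "synthetic", seed = as.integer(seed), n_genes = n_genes,
         n_per_group = n_per_group, n_de = n_de,
         effect_log2fc = effect_log2fc, noise_sd = noise_sd,
         p_edge = p_edge, clique_size = clique_size, n_overlap = n_overlap,
         n_source_extra = n_source_extra, n_sets = n_sets,
         set_size_range = set_size_range,
         score_threshold = score_threshold, deg_method = deg_method,
         fc_threshold = fc_threshold, p_threshold = p_threshold,
         hub_rule = hub_rule, hub_k = hub_k, pathway = pathway,
         mcode = mcode),
    class = "pipeline_config"
  )
}

#' Run the full prioritization pipeline
#'
#' Executes every stage in order (DEG screen, disease-set assembly,
#' network construction, Nim centrality and module detection, enrichment,
#' triple intersection) and returns the report with full provenance. With
#' a synthetic configuration ([synthetic_config()]) all inputs are
#' generated from the config's seed, so identical configs give identical
#' reports. Any stage failure aborts with the stage name in the message.
#'
#' @param config A `pipeline_config` (currently from
#'   [synthetic_config()]).
#' @param out_dir Optional directory; when given, every intermediate table
#'   (expression, edges, GMT, DEG table, Nim table, modules, enrichment)
#'   and the final report JSON are written there as flat files.
#' @return A `prioritization_report` with additional fields: `truth` (the
#'   merged planted [synthetic_truth()]), `network` (the thresholded
#'   `ppi_network`), `deg` (the DEG table),
#'   `nim_table`, `modules`, `enrichment`, `disease_set`, `config_echo`,
#'   `log`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    log[[length(log) + 1L]] <<- paste0(...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- config$seed

  # --- inputs (synthetic, planted) -----------------------------------
  sim <- stage("simulate", {
    expr <- simulate_expression(config$n_genes, config$n_per_group,
                                config$n_de, config$effect_log2fc,
                                config$noise_sd, seed)
    ppi <- simulate_ppi(config$n_genes, config$p_edge, config$clique_size,
                        seed + 1L)
    genes <- rownames(expr$matrix$values)
    planted <- genes[seq_len(config$n_overlap)]
    gs <- simulate_genesets(genes, config$n_sets, config$set_size_range,
                            planted, seed + 2L)
    n_known <- min(config$n_de + config$n_source_extra, config$n_genes)
    sources <- simulate_sources(genes, genes[seq_len(n_known)],
                                seed = seed + 3L)
    planted_set <- gs$collection$sets[[gs$truth$enriched_set_id]]
    truth <- synthetic_truth(
      de_genes = expr$truth$de_genes,
      clique_genes = ppi$truth$clique_genes,
      enriched_set_id = gs$truth$enriched_set_id,
      target_genes = intersect(ppi$truth$clique_genes, planted_set),
      seed = seed
    )
    list(expr = expr$matrix, edges = ppi$edges, collection = gs$collection,
         sources = sources, truth = truth)
  })
  note("simulate: ", config$n_genes, " genes, planted clique of ",
       config$clique_size, ", planted set ", sim$truth$enriched_set_id)

  # --- differential expression ---------------------------------------
  deg <- stage("deg", test_two_groups(sim$expr, config$deg_method))
  screened <- stage("deg", screen_degs(deg, config$fc_threshold,
                                       config$p_threshold))
  deg_genes <- c(screened$up, screened$down)
  note("deg: ", length(screened$up), " up, ", length(screened$down),
       " down")

  # --- disease gene set ----------------------------------------------
  disease_set <- stage("assemble",
                       assemble_disease_set(deg_genes, sim$sources))
  note("assemble: ", length(disease_set), " disease genes")

  # --- PPI network ----------------------------------------------------
  net <- stage("network", build_network(sim$edges, config$score_threshold,
                                        restrict_to = disease_set))
  note("network: ", length(network_nodes(net)), " nodes, ",
       nrow(network_edges(net)), " edges at score > ",
       config$score_threshold)

  # --- centrality + modules ------------------------------------------
  nim_table <- stage("nim", compute_nim(net))
  hubs <- stage("nim", withCallingHandlers(
    select_hubs(nim_table, config$hub_rule, config$hub_k),
    warning = function(w) {
      note("nim: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  ))
  note("nim: ", length(hubs), " hubs by rule `", config$hub_rule, "`")
  modules <- stage("mcode", find_modules(net, config$mcode))
  module_genes <- if (length(modules)) modules[[1]]$members else character()
  note("mcode: ", length(modules), " modules; top module has ",
       length(module_genes), " members")

  # --- enrichment -----------------------------------------------------
  enrichment <- stage("enrich",
                      suppressMessages(enrich(disease_set, sim$collection)))
  pathway_id <- config$pathway
  if (is.null(pathway_id)) pathway_id <- sim$truth$enriched_set_id
  pathway_genes <- stage("enrich", genes_in_set(sim$collection, pathway_id,
                                                network_nodes(net)))
  note("enrich: ", sum(enrichment$passes), " set(s) pass; pathway `",
       pathway_id, "` has ", length(pathway_genes),
       " members in the network")

  # --- intersection ---------------------------------------------------
  report <- prioritize(module_genes, hubs, pathway_genes)
  note("prioritize: ", length(report$intersection), " target(s): ",
       paste(report$intersection, collapse = ", "))

  report$truth <- sim$truth
  report$network <- net
  report$deg <- deg
  report$nim_table <- nim_table
  report$modules <- modules
  report$enrichment <- enrichment
  report$disease_set <- disease_set
  report$config_echo <- config
  report$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_expression_tsv(sim$expr, p("expression.tsv"))
    write_edges_tsv(sim$edges, p("edges.tsv"))
    write_gmt(sim$collection, p("genesets.gmt"))
    write.table(deg, p("deg.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(nim_table, p("nim.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    mod_df <- data.frame(
      module_id = seq_along(modules),
      score = vapply(modules, `[[`, numeric(1), "score"),
      size = vapply(modules, function(m) length(m$members), integer(1)),
      members = vapply(modules, function(m) {
        paste(m$members, collapse = ";")
      }, character(1))
    )
    write.table(mod_df, p("modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(enrichment, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(disease_set, p("disease_set.txt"))
    report_out <- report[c("module_genes", "nim_top", "pathway_genes",
                           "intersection", "disease_set", "log")]
    report_out$truth <- unclass(sim$truth)
    write_json_report(report_out, p("report.json"))
  }
  report
}
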