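test_that("simulate_expression plants the requested effects", {
  sim <- simulate_expression(100, 32, 10, effect_log2fc = 2, noise_sd = 0.5,
                             seed = 7)
  expect_s3_class(sim$matrix, "expr_matrix")
  expect_equal(dim(sim$matrix$values), c(100, 64))
  expect_length(sim$truth$de_genes, 10)

  # planted group-mean gap is effect +- noise; half up, half down
  case <- sim$matrix$groups == "case"
  gap <- rowMeans(sim$matrix$values[, case]) -
    rowMeans(sim$matrix$values[, !case])
  planted <- rownames(sim$matrix$values) %in% sim$truth$de_genes
  expect_equal(sum(gap[planted] > 0), 5)
  expect_true(all(abs(abs(gap[planted]) - 2) < 0.6))
  expect_true(all(abs(gap[!planted]) < 0.6))

  # null case: no planted genes
  null_sim <- simulate_expression(100, 32, 0, 2, 1, seed = 7)
  expect_length(null_sim$truth$de_genes, 0)
})

test_that("simulate_expression is seed-deterministic and validates", {
  a <- simulate_expression(50, 4, 5, 2, 0.5, seed = 7)
  b <- simulate_expression(50, 4, 5, 2, 0.5, seed = 7)
  c <- simulate_expression(50, 4, 5, 2, 0.5, seed = 8)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_false(identical(a$matrix$values, c$matrix$values))

  expect_error(simulate_expression(10, 4, 11, 2, 0.5, 1), "n_de")
  expect_error(simulate_expression(10, 4, 2, 2, 0, 1), "noise_sd")
  expect_error(simulate_expression(10, 1, 2, 2, 1, 1), "at least 2")
})

test_that("simulate_ppi plants a pairwise-adjacent clique with high scores", {
  sim <- simulate_ppi(30, 0.05, 6, seed = 1)
  g <- sim$network$graph
  clique <- sim$truth$clique_genes
  expect_length(clique, 6)
  sub <- igraph::induced_subgraph(g, clique)
  expect_equal(igraph::ecount(sub), choose(6, 2))
  expect_true(all(igraph::E(sub)$score > 0.9))

  # near-zero background: only the clique edges remain
  sparse <- simulate_ppi(30, 1e-9, 6, seed = 1)
  expect_equal(nrow(sparse$edges), choose(6, 2))

  a <- simulate_ppi(30, 0.05, 6, seed = 2)$edges
  b <- simulate_ppi(30, 0.05, 6, seed = 2)$edges
  expect_identical(a, b)
  expect_error(simulate_ppi(30, 1.2, 6, 1), "p_edge")
  expect_error(simulate_ppi(5, 0.1, 6, 1), "clique_size")
})

test_that("simulate_genesets plants one superset and round-trips via GMT", {
  universe <- sprintf("G%04d", 1:50)
  planted <- c("G0001", "G0002", "G0003")
  sim <- simulate_genesets(universe, 10, c(5, 10), planted, seed = 3)
  members <- sim$collection$sets[[sim$truth$enriched_set_id]]
  expect_true(all(planted %in% members))
  expect_length(sim$collection$sets, 10)

  one <- simulate_genesets(universe, 1, c(5, 10), planted, seed = 3)
  expect_length(one$collection$sets, 1)

  expect_error(simulate_genesets(universe, 5, c(5, 10), c("XX"), 1),
               "universe")

  # determinism through the GMT writer
  f1 <- withr::local_tempfile(fileext = ".gmt")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sim$collection, f1)
  write_gmt(simulate_genesets(universe, 10, c(5, 10), planted,
                              seed = 3)$collection, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_gmt(f1)
  expect_identical(back$sets, sim$collection$sets)
})

test_that("simulate_sources yields tables whose filters recover only hits", {
  universe <- sprintf("G%04d", 1:100)
  disease <- universe[1:10]
  src <- simulate_sources(universe, disease, n_hits_per_source = 4,
                          n_decoys_per_source = 6, seed = 5)
  expect_named(src, c("CTD", "DisGeNET", "GeneCards", "OMIM", "PharmGKB",
                      "TTD"))
  for (s in src) {
    kept <- filter_source(s)
    expect_true(all(kept %in% disease))
    expect_gt(length(kept), 0)
  }
})
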