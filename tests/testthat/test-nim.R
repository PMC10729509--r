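test_that("Nim matches closed forms on path and star graphs", {
  nt <- compute_nim(new_network(path_graph(c("A", "B", "C"))))
  b <- nt[nt$node == "B", ]
  expect_equal(b$betweenness, 1)
  expect_equal(b$exp_closeness, 2 * exp(-1))
  expect_equal(b$nim, sqrt(2 * exp(-1)), tolerance = 1e-12)
  expect_equal(nt$nim[nt$node %in% c("A", "C")], c(0, 0))

  star <- compute_nim(new_network(star_graph("C0", paste0("L", 1:4))))
  ctr <- star[star$node == "C0", ]
  expect_equal(ctr$betweenness, choose(4, 2))
  expect_equal(ctr$nim, sqrt(6 * 4 * exp(-1)), tolerance = 1e-12)
  expect_equal(star$nim[star$node != "C0"], rep(0, 4))

  # table invariants
  expect_equal(nt$nim^2, nt$betweenness * nt$exp_closeness)
  expect_true(all(nt$nim[nt$betweenness == 0] == 0))
})

test_that("betweenness term matches the brute-force pair-sum oracle", {
  for (seed in 1:8) {
    net <- new_network(random_edge_table(40, 0.08, seed))
    nt <- compute_nim(net)
    oracle_b <- brute_betweenness(net)[nt$node]
    oracle_c <- brute_exp_closeness(net)[nt$node]
    scale <- max(nt$nim, 1)
    expect_lt(max(abs(nt$betweenness - oracle_b)), 1e-9 * max(oracle_b, 1))
    expect_lt(max(abs(nt$exp_closeness - oracle_c)), 1e-12 * 40)
    expect_lt(max(abs(nt$nim - sqrt(oracle_b * oracle_c))) / scale, 1e-9)
    # and against the classic textbook implementation
    ig <- igraph::betweenness(net$graph, directed = FALSE)[nt$node]
    expect_equal(nt$betweenness, unname(ig), tolerance = 1e-9)
  }
})

test_that("Nim is equivariant under node relabeling", {
  tab <- random_edge_table(20, 0.15, seed = 3)
  nt1 <- compute_nim(new_network(tab))
  relabel <- setNames(sprintf("Z%02d", 20:1),
                      sort(unique(c(tab$a, tab$b))))
  tab2 <- data.frame(a = relabel[tab$a], b = relabel[tab$b], score = 1)
  nt2 <- compute_nim(new_network(tab2))
  m <- match(relabel[nt1$node], nt2$node)
  expect_equal(nt1$nim, nt2$nim[m], tolerance = 1e-12)
})

test_that("a pendant leaf adds exactly exp(-1) to its anchor's closeness", {
  tab <- random_edge_table(15, 0.2, seed = 5)
  net <- new_network(tab)
  anchor <- network_nodes(net)[1]
  before <- compute_nim(net)
  with_leaf <- new_network(rbind(tab, data.frame(a = anchor, b = "LEAF",
                                                 score = 1)))
  after <- compute_nim(with_leaf)
  expect_equal(after$exp_closeness[after$node == anchor],
               before$exp_closeness[before$node == anchor] + exp(-1),
               tolerance = 1e-12)
  # the leaf itself mediates nothing
  expect_equal(after$nim[after$node == "LEAF"], 0)
})

test_that("select_hubs implements both rules with deterministic ties", {
  nt <- compute_nim(new_network(path_graph(c("A", "B", "C"))))
  expect_identical(select_hubs(nt, "above_mean"), "B")
  expect_identical(select_hubs(nt, "top_k", k = 1), "B")

  # all-equal nim: strict mean comparison selects nothing
  tri <- compute_nim(new_network(complete_graph(c("A", "B", "C"))))
  expect_identical(select_hubs(tri, "above_mean"), character(0))

  # k beyond the node count returns everything with a warning
  expect_warning(all_nodes <- select_hubs(tri, "top_k", k = 10), "exceeds")
  expect_identical(all_nodes, c("A", "B", "C"))

  # equal-nim ties break lexicographically
  expect_identical(select_hubs(tri, "top_k", k = 2), c("A", "B"))
  expect_error(select_hubs(nt[0, ], "top_k"), "empty")
})

test_that("planted clique nodes dominate the top-k ranking", {
  sim <- simulate_ppi(60, 0.05, 8, seed = 4)
  net <- build_network(sim$edges, 0.9)
  nt <- compute_nim(net)
  hubs <- select_hubs(nt, "top_k", k = 8)
  expect_gte(length(intersect(hubs, sim$truth$clique_genes)), 5)
})
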