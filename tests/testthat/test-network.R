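test_that("build_network filters, rescales and symmetrizes", {
  rows <- data.frame(
    a = c("A", "A", "B", "A", "C"),
    b = c("B", "B", "A", "C", "C"),
    score = c(0.95, 0.92, 0.95, 0.85, 0.99)
  )
  # (A,B) duplicated both ways -> one edge at max score; (A,C) below 0.9
  # dropped; (C,C) self-loop dropped -> graph is the single A-B edge
  net <- build_network(rows, 0.9)
  expect_identical(sort(network_nodes(net)), c("A", "B"))
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$score, 0.95)

  # 0-1000 dialect detection
  net2 <- build_network(data.frame(a = "A", b = "B", score = 950), 0.9)
  expect_equal(network_edges(net2)$score, 0.95)
  expect_error(build_network(data.frame(a = "A", b = "B", score = 850), 0.9),
               "empty network")

  # restriction on both endpoints
  rows3 <- data.frame(a = c("A", "C"), b = c("B", "D"),
                      score = c(0.95, 0.95))
  net3 <- build_network(rows3, 0.9, restrict_to = c("A", "B", "C"))
  expect_identical(sort(network_nodes(net3)), c("A", "B"))

  # malformed rows are skipped with a warning
  rows4 <- data.frame(a = c("A", ""), b = c("B", "C"),
                      score = c("0.95", "bad"))
  expect_warning(net4 <- build_network(rows4, 0.9), "malformed")
  expect_identical(sort(network_nodes(net4)), c("A", "B"))

  expect_error(build_network(rows, 1.5), "score_threshold")
})

test_that("shortest_paths_from returns BFS distances and path counts", {
  tri <- new_network(complete_graph(c("A", "B", "C")))
  sp <- shortest_paths_from(tri, "A")
  expect_equal(sp$dist[c("A", "B", "C")], c(A = 0, B = 1, C = 1))
  expect_equal(sp$sigma[c("A", "B", "C")], c(A = 1, B = 1, C = 1))

  # 4-cycle: two equal-length routes A -> C
  cyc <- new_network(edges_of(cbind(c("A", "B", "C", "D"),
                                    c("B", "C", "D", "A"))))
  sp <- shortest_paths_from(cyc, "A")
  expect_equal(unname(sp$sigma["C"]), 2)
  expect_equal(unname(sp$dist["C"]), 2)

  # disconnected node: Inf distance, zero count
  two <- new_network(edges_of(rbind(c("A", "B"), c("C", "D"))))
  sp <- shortest_paths_from(two, "A")
  expect_equal(unname(sp$dist["C"]), Inf)
  expect_equal(unname(sp$sigma["C"]), 0)

  expect_error(shortest_paths_from(tri, "Z"), "not in the network")
})

test_that("sigma matches layered-DAG enumeration on random graphs", {
  for (seed in 1:5) {
    net <- new_network(random_edge_table(30, 0.1, seed))
    g <- net$graph
    d <- igraph::distances(g)
    nodes <- network_nodes(net)
    # oracle sigma via the independent DP in helper-oracles.R
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    for (s in nodes[1:5]) {
      sp <- shortest_paths_from(net, s)
      si <- match(s, nodes)
      for (t in nodes) {
        ti <- match(t, nodes)
        if (ti == si || is.infinite(d[si, ti])) next
        pred <- which(adj[, ti] & d[si, ] == d[si, ti] - 1)
        # Brandes recursion identity: sigma_st = sum over predecessors
        if (d[si, ti] > 1) {
          expect_equal(unname(sp$sigma[t]), sum(sp$sigma[nodes[pred]]))
        }
      }
    }
  }
})

test_that("hop distance is a metric on each component", {
  net <- new_network(random_edge_table(25, 0.15, seed = 9))
  d <- sapply(network_nodes(net),
              function(s) shortest_paths_from(net, s)$dist)
  expect_equal(d, t(d)) # symmetry
  n <- nrow(d)
  set.seed(1)
  for (rep in 1:200) {
    ijk <- sample.int(n, 3)
    fin <- is.finite(d[ijk[1], ijk[2]]) && is.finite(d[ijk[2], ijk[3]])
    if (fin) {
      expect_lte(d[ijk[1], ijk[3]], d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]])
    }
  }
})

test_that("edge tables round-trip through the STRING-style writer", {
  edges <- data.frame(protein1 = c("A", "B"), protein2 = c("B", "C"),
                      combined_score = c(0.95, 0.91))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(edges, f)
  back <- read_edges_tsv(f)
  expect_equal(back, edges)
  # headerless space-separated dialect
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A B 0.95", "B C 0.91"), f2)
  back2 <- read_edges_tsv(f2)
  expect_equal(back2$combined_score, c(0.95, 0.91))
})
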