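test_that("hypergeom_tail handles boundaries and a hand-counted case", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
  # set = universe: the whole query overlaps, tail is 1
  expect_equal(hypergeom_tail(5, 20, 5, 20), 1)
  # C(5,3)C(15,2)+C(5,4)C(15,1)+C(5,5) over C(20,5) = 1126/15504
  expect_equal(hypergeom_tail(3, 5, 5, 20), 1126 / 15504,
               tolerance = 1e-12)
  expect_error(hypergeom_tail(6, 5, 5, 20), "inconsistent")
  expect_error(hypergeom_tail(1, 30, 5, 20), "inconsistent")
})

test_that("hypergeom_tail matches exact enumeration over all N <= 25", {
  worst <- 0
  for (N in 2:25) {
    for (K in 1:N) {
      for (n in 1:N) {
        for (k in 0:min(K, n)) {
          # overlap below max(0, n-(N-K)) is impossible; tail still defined
          got <- hypergeom_tail(k, K, n, N)
          want <- enum_hyper_tail(k, K, n, N)
          worst <- max(worst, abs(got - want) / max(want, 1e-300))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("bh_adjust is the step-up with monotonicity, order preserved", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(4)
  p <- runif(50)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
})

test_that("enrich recovers a strongly planted set and drops k = 0 sets", {
  universe <- sprintf("G%04d", 1:200)
  planted <- universe[1:15]
  sim <- simulate_genesets(universe, 25, c(10, 20), planted, seed = 13)
  res <- enrich(planted, sim$collection)
  expect_identical(res$set_id[1], sim$truth$enriched_set_id)
  expect_true(res$passes[1])
  expect_true(all(res$k >= 1))
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_identical(res$q_value, res$p_adjusted)

  # collection order does not matter
  shuffled <- sim$collection
  perm <- rev(seq_along(shuffled$sets))
  shuffled$sets <- shuffled$sets[perm]
  shuffled$description <- shuffled$description[perm]
  res2 <- enrich(planted, shuffled)
  expect_equal(res2[order(res2$set_id), ], res[order(res$set_id), ],
               ignore_attr = TRUE)

  expect_error(enrich(c("NOT_THERE"), sim$collection), "universe")
})

test_that("genes_in_set restricts membership correctly", {
  coll <- geneset_collection(list(S1 = c("A", "B", "C"), S2 = c("C", "D")))
  expect_identical(genes_in_set(coll, "S1", coll$universe),
                   c("A", "B", "C"))
  expect_identical(genes_in_set(coll, "S1", character()), character(0))
  expect_identical(genes_in_set(coll, "S1", c("B", "Z")), "B")
  expect_error(genes_in_set(coll, "NOPE", "A"), "unknown set id")
})

test_that("random queries rarely pass the planted set at p < 0.05", {
  universe <- sprintf("G%04d", 1:300)
  planted <- universe[1:10]
  sim <- simulate_genesets(universe, 20, c(10, 25), planted, seed = 17)
  set.seed(99)
  hits <- vapply(1:400, function(i) {
    q <- sample(universe, 30)
    res <- enrich(q, sim$collection, p_cut = 0.05, q_cut = 1)
    row <- res[res$set_id == sim$truth$enriched_set_id, ]
    nrow(row) > 0 && row$p_value < 0.05
  }, logical(1))
  # discrete conservative test: type-I at or below nominal 5%
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})
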