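test_that("similarity indices reproduce hand-computed values", {
  expect_equal(binary_jaccard(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(binary_jaccard(c("a"), c("b")), 0)
  expect_equal(binary_jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(binary_jaccard(character(0), character(0)), 0)

  expect_equal(weighted_jaccard(c(2, 1), c(2, 1)), 1)
  expect_equal(weighted_jaccard(c(2, 0), c(0, 3)), 0)
  expect_equal(weighted_jaccard(c(2, 1), c(1, 1)), 2 / 3)

  expect_equal(tanimoto(c(3, 2), c(3, 2)), 1)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0)
  expect_equal(tanimoto(c(1, 1), c(1, 0)), 0.5)
  expect_error(tanimoto(c(0, 0), c(0, 0)), "zero")

  # named count vectors align on the union of names
  expect_equal(weighted_jaccard(c(x = 2, y = 1), c(y = 1, z = 1)), 0.25)
})

test_that("indices are symmetric, bounded, and 1 on identical inputs", {
  set.seed(41)
  for (i in 1:20) {
    a <- rpois(6, 1)
    b <- rpois(6, 1)
    for (f in list(weighted_jaccard,
                   function(x, y) if (sum(x) + sum(y) > 0 &&
                                      sum(x * y) + sum((x - y)^2) > 0)
                     tanimoto(x, y) else 0)) {
      v <- f(a, b)
      expect_gte(v, 0)
      expect_lte(v, 1)
      expect_equal(v, f(b, a))
    }
    if (sum(a) > 0) {
      expect_equal(weighted_jaccard(a, a), 1)
      expect_equal(tanimoto(a, a), 1)
    }
  }
})

test_that("the permutation null conserves counts and the spacer multiset", {
  co <- simulate_cohort(n_isolates = 12, n_modules = 3, pool_size = 20,
                        seed = 5)
  cl <- cluster_spacers(co$spacers)
  null <- permutation_null(cl, n_replicates = 25, seed = 2,
                           keep_replicates = TRUE)
  orig <- null$original_assignment
  for (rep in null$replicates) {
    expect_identical(sort(rep), sort(orig$cluster))      # global multiset
  }
  expect_true(all(null$values >= 0 & null$values <= 1))
  # determinism under the seed
  null2 <- permutation_null(cl, n_replicates = 25, seed = 2)
  expect_identical(null$values, null2$values)
  expect_error(permutation_null(cl, n_replicates = 0), ">= 1")
})

test_that("nearest-rank thresholds behave at the boundaries", {
  expect_equal(threshold_from_null(rep(0, 50), 95), 0)
  grid <- seq(0.01, 1, by = 0.01)
  expect_equal(threshold_from_null(grid, 95), 0.95)
  expect_equal(threshold_from_null(grid, 100), 1)
  # monotone in the percentile
  set.seed(42)
  v <- runif(500)
  ps <- c(10, 25, 50, 75, 90, 95, 99, 100)
  ts <- vapply(ps, function(p) threshold_from_null(v, p), numeric(1))
  expect_true(all(diff(ts) >= 0))
  expect_error(threshold_from_null(numeric(0)), "empty")
})

# three isolates engineered so A-B has Jaccard 0.5 and B-C 0.05
three_isolate_fixture <- function() {
  sp <- list(
    A = c("s1", "s2"),
    B = c("s1", "s2", "s3", "s4"),
    C = c("s4", paste0("t", 1:16))
  )
  tibble::tibble(
    isolate_id = rep(names(sp), lengths(sp)),
    spacer_id = paste0("r", seq_len(sum(lengths(sp)))),
    cluster_id = unlist(sp, use.names = FALSE),
    sequence = unlist(sp, use.names = FALSE)
  )
}

test_that("edge thresholding keeps the boundary and removes below it", {
  cl <- three_isolate_fixture()
  edges <- pairwise_similarity(cl)
  expect_equal(edges$jaccard_binary[edges$isolate_a == "A" &
                                      edges$isolate_b == "B"], 0.5)
  expect_equal(edges$jaccard_binary[edges$isolate_a == "B" &
                                      edges$isolate_b == "C"], 1 / 20)

  g0 <- build_network(cl, threshold = 0)
  expect_equal(igraph::ecount(g0), 2)     # all sharing pairs
  g12 <- build_network(cl, threshold = 0.12)
  expect_equal(igraph::ecount(g12), 1)    # only A-B survives
  ghigh <- build_network(cl, threshold = 1.01)
  expect_equal(igraph::ecount(ghigh), 0)
  # boundary inclusive: an edge exactly at the threshold is kept
  gb <- build_network(cl, threshold = 0.5)
  expect_equal(igraph::ecount(gb), 1)
})

test_that("raising the threshold never adds edges", {
  co <- simulate_cohort(n_isolates = 15, n_modules = 3, pool_size = 20,
                        seed = 6)
  cl <- cluster_spacers(co$spacers)
  prev <- Inf
  for (t in c(0, 0.05, 0.12, 0.3, 0.6, 1)) {
    e <- igraph::ecount(build_network(cl, threshold = t))
    expect_lte(e, prev)
    prev <- e
  }
})

test_that("module detection handles cliques, empty graphs, and singletons", {
  # two disjoint cliques -> 2 modules for every method
  el <- rbind(t(combn(paste0("a", 1:4), 2)), t(combn(paste0("b", 1:4), 2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  for (m in c("greedy-modularity", "label-propagation",
              "connected-components")) {
    part <- detect_modules(g, method = m, seed = 1)
    expect_equal(max(part$module), 2)
    within_a <- part$module[grepl("^a", part$isolate_id)]
    expect_equal(length(unique(within_a)), 1)
  }
  # edgeless graph: every node its own singleton module
  g0 <- igraph::make_empty_graph(n = 5, directed = FALSE)
  igraph::V(g0)$name <- paste0("n", 1:5)
  part0 <- detect_modules(g0, method = "connected-components")
  expect_equal(max(part0$module), 5)
  expect_error(detect_modules(g, method = "mystery"), "arg")
})
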