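test_that("position MAD is the unscaled median absolute deviation", {
  expect_equal(position_mad(c(7, 7, 7)), 0)
  expect_equal(position_mad(c(10, 12, 14)), 2)
  expect_equal(position_mad(c(1, 2, 3, 4, 100)), 1)
  expect_equal(position_mad(5), 0)
  expect_error(position_mad(numeric(0)), "empty")

  set.seed(61)
  x <- rnorm(25, 500, 40)
  expect_equal(position_mad(x + 1e6), position_mad(x))   # translation
  expect_equal(position_mad(3 * x), 3 * position_mad(x)) # scaling
})

fake_hits <- function(subject_id, starts, len = 32L) {
  tibble::tibble(
    spacer_id = paste0("s", seq_along(starts)), subject_id = subject_id,
    start = as.integer(starts), end = as.integer(starts) + len - 1L,
    strand = "+", mismatches = 0L, masked = FALSE,
    mask_reason = NA_character_
  )
}

test_that("target summaries require two hits for a MAD", {
  h <- dplyr::bind_rows(fake_hits("g1", c(100, 200, 300)),
                        fake_hits("g2", 500))
  s <- summarize_targets(h, c(g1 = 10000L, g2 = 10000L))
  expect_equal(s$n_hits[s$subject_id == "g1"], 3)
  expect_equal(s$mad[s$subject_id == "g1"], 100)
  expect_true(is.na(s$mad[s$subject_id == "g2"]))
  # masked hits never contribute
  hm <- fake_hits("g3", c(1, 50))
  hm$masked <- TRUE
  expect_equal(nrow(summarize_targets(dplyr::bind_rows(h, hm))), 2)
})

test_that("region calling spans min-max hits with clipped flanks", {
  starts <- as.integer(seq(100000, 150000, length.out = 12))
  h <- fake_hits("g1", starts)
  r <- call_regions(h, c(g1 = 1000000L), min_hits = 10, flank = 25000)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 75000L)
  expect_equal(r$end, max(h$end) + 25000L)
  expect_equal(r$n_support, 12L)

  # nine hits: below the cut-off, no region
  expect_equal(nrow(call_regions(fake_hits("g1", starts[1:9]),
                                 c(g1 = 1000000L), min_hits = 10)), 0)

  # clipping at the origin and the end
  hc <- fake_hits("g2", as.integer(seq(5000, 95000, length.out = 10)))
  rc <- call_regions(hc, c(g2 = 100000L), min_hits = 10, flank = 25000)
  expect_equal(rc$start, 1L)
  expect_equal(rc$end, 100000L)
  expect_error(call_regions(h, c(g1 = 1e6), flank = -5), "non-negative")
})

test_that("pairwise identity tracks planted divergence and containment", {
  a <- simulate_genome(4000, 0.5, seed = 62)
  expect_equal(pairwise_identity(a, a)$identity, 100)
  expect_equal(pairwise_identity(a, a)$coverage, 100)

  set.seed(63)
  b <- mutate_k(a, 200)  # 5% divergence
  pi <- pairwise_identity(a, b)
  # identity within 3 binomial sd of 95%
  expect_lt(abs(pi$identity - 95), 100 * 3 * sqrt(0.05 * 0.95 / 4000) + 0.5)
  expect_gt(pi$coverage, 95)

  # containment: coverage is relative to the shorter sequence
  half <- substr(a, 1, 2000)
  pc <- pairwise_identity(a, half)
  expect_equal(pc$identity, 100)
  expect_equal(pc$coverage, 100)

  # symmetric by construction, and strand-aware
  expect_equal(pairwise_identity(b, a), pairwise_identity(a, b))
  prc <- pairwise_identity(a, revcomp(a))
  expect_equal(prc$identity, 100)
  expect_equal(prc$strand, "-")
  expect_error(pairwise_identity("", "ACGT"), "non-empty")
})

test_that("anchored identity agrees with an alignment oracle on substitutions", {
  a <- simulate_genome(1500, 0.5, seed = 64)
  set.seed(65)
  b <- mutate_k(a, 60)
  got <- pairwise_identity(a, b)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  expect_lt(abs(got$identity - Biostrings::pid(aln)), 0.5)
})

test_that("the dedup graph links species-level duplicates only", {
  a <- simulate_genome(3000, 0.5, seed = 66)
  set.seed(67)
  dup1 <- mutate_k(a, 60)    # 2% divergence
  dup2 <- mutate_k(a, 90)    # 3% divergence
  other <- simulate_genome(3000, 0.5, seed = 68)
  g <- dedup_graph(c(a = a, d1 = dup1, d2 = dup2, x = other))
  expect_equal(igraph::vcount(g), 4)
  # a, d1, d2 form a triangle; x stays isolated
  expect_equal(igraph::ecount(g), 3)
  expect_equal(igraph::degree(g)[["x"]], 0)
})

test_that("MCL respects components and splits the barbell", {
  # two disconnected cliques
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  cl <- mcl_cluster(A, inflation = 2)
  expect_equal(max(cl$cluster), 2)
  expect_equal(length(unique(cl$cluster[1:4])), 1)

  # singleton node
  single <- mcl_cluster(matrix(0, 1, 1))
  expect_equal(nrow(single), 1)
  expect_equal(single$cluster, 1L)

  # barbell: two K5s joined by one edge split at inflation 2
  B <- matrix(0, 10, 10)
  B[1:5, 1:5] <- 1
  B[6:10, 6:10] <- 1
  diag(B) <- 0
  B[5, 6] <- B[6, 5] <- 1
  bc <- mcl_cluster(B, inflation = 2)
  expect_equal(max(bc$cluster), 2)
  expect_equal(sort(table(bc$cluster)), sort(c(`1` = 5L, `2` = 5L)),
               ignore_attr = TRUE)
  expect_error(mcl_cluster(B, inflation = 1), "> 1")
})

test_that("MCL output is a partition and never merges components", {
  set.seed(69)
  for (i in 1:10) {
    g <- igraph::sample_gnp(12, 0.2)
    igraph::V(g)$name <- paste0("v", 1:12)
    comp <- igraph::components(g)$membership
    cl <- mcl_cluster(g, inflation = 2)
    expect_equal(nrow(cl), 12)
    expect_equal(anyDuplicated(cl$id), 0)
    # each MCL cluster lies within one connected component
    for (k in unique(cl$cluster)) {
      members <- cl$id[cl$cluster == k]
      expect_equal(length(unique(comp[members])), 1)
    }
  }
})

test_that("representatives are the longest member with lexical tie-break", {
  A <- matrix(1, 3, 3) - diag(3)
  rownames(A) <- colnames(A) <- c("b", "a", "c")
  lens <- c(a = 100, b = 300, c = 300)
  cl <- mcl_cluster(A, seq_lengths = lens)
  expect_true(all(cl$representative == "b"))
  cl2 <- mcl_cluster(A)
  expect_true(all(cl2$representative == "a"))
})

test_that("lifestyle flag is a keyword heuristic over products", {
  expect_equal(lifestyle_flag("phage integrase"), "temperate")
  expect_equal(lifestyle_flag(c("hypothetical protein",
                                "serine recombinase family")), "temperate")
  expect_equal(lifestyle_flag("major capsid protein"),
               "virulent-or-unknown")
  expect_equal(lifestyle_flag(character(0)), "virulent-or-unknown")
})
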