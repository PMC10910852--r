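test_that("genome simulation is deterministic and honours the GC dial", {
  expect_identical(simulate_genome(100, 0.5, seed = 1),
                   simulate_genome(100, 0.5, seed = 1))
  expect_false(simulate_genome(100, 0.5, seed = 1) ==
                 simulate_genome(100, 0.5, seed = 2))
  at_only <- simulate_genome(50, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", at_only))
  gc_only <- simulate_genome(50, gc = 1, seed = 1)
  expect_true(grepl("^[GC]+$", gc_only))
  expect_error(simulate_genome(0), "positive")
  expect_error(simulate_genome(10, gc = 1.2), "\\[0, 1\\]")

  # observed GC within 3 binomial standard deviations of the target
  n <- 100000
  g <- simulate_genome(n, 0.5, seed = 7)
  gc_hat <- mean(chars(g) %in% c("G", "C"))
  expect_lt(abs(gc_hat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("prophage implantation records exact intervals", {
  genome <- simulate_genome(1e6, 0.5, seed = 3)
  phage <- simulate_genome(40000, 0.5, seed = 4)
  imp <- implant_prophage(genome, phage, 100001)
  expect_equal(unname(imp$interval), c(100001, 140000))
  expect_equal(nchar(imp$sequence), 1e6)
  expect_identical(substr(imp$sequence, 100001, 140000), phage)

  expect_error(implant_prophage(genome, phage, 1e6 - 100), "bounds")

  imp2 <- implant_prophage(imp$sequence, phage, 500001)
  expect_true(imp2$interval["start"] > imp$interval["end"])

  ins <- implant_prophage("AAAA", "CC", 3, mode = "insert")
  expect_identical(ins$sequence, "AACCAA")
})

test_that("array implantation builds repeat-spacer-repeat cassettes", {
  r <- "GGGGG"
  out <- implant_crispr_array(strrep("A", 40), r, c("TTT", "CCC"), 5)
  expect_identical(out$cassette, "GGGGGTTTGGGGGCCCGGGGG")
  expect_error(implant_crispr_array(strrep("A", 40), r, character(0), 5),
               "at least one")
})

test_that("implanted arrays round-trip through extraction", {
  set.seed(42)
  spacers <- replicate(4, rand_dna(32))
  genome <- simulate_genome(5000, 0.5, seed = 5)
  out <- implant_crispr_array(genome, crispr1_repeat, spacers, 1000)
  arr <- extract_spacers(out$sequence, isolate_id = "g1")
  expect_identical(arr$sequence, spacers)
  expect_equal(attr(arr, "source_interval"),
               unname(out$interval))
})

test_that("cohort simulation conserves counts and is seed-deterministic", {
  co1 <- simulate_cohort(n_isolates = 20, n_modules = 4, pool_size = 30,
                         seed = 11)
  co2 <- simulate_cohort(n_isolates = 20, n_modules = 4, pool_size = 30,
                         seed = 11)
  expect_identical(co1$spacers, co2$spacers)
  expect_identical(co1$truth$phages, co2$truth$phages)

  sp <- co1$spacers
  per_iso <- table(sp$isolate_id)
  expect_equal(sum(per_iso), nrow(sp))
  expect_true(all(per_iso >= 6 & per_iso <= 16))
  expect_setequal(unique(sp$isolate_id),
                  co1$truth$module_labels$isolate_id)
  # every spacer has a truth record
  expect_true(all(sp$spacer_id %in% co1$truth$spacer_origins$spacer_id))
})

test_that("decoy_fraction = 1 yields a cohort of pure decoys", {
  co <- simulate_cohort(n_isolates = 8, n_modules = 2, pool_size = 20,
                        decoy_fraction = 1, seed = 2)
  org <- co$truth$spacer_origins
  used <- org[org$spacer_id %in% co$spacers$spacer_id, ]
  expect_true(all(used$origin == "decoy"))
})

test_that("single-module cohorts share one pool with high pairwise overlap", {
  co <- simulate_cohort(n_isolates = 10, n_modules = 1, pool_size = 30,
                        decoy_fraction = 0, seed = 9)
  cl <- cluster_spacers(co$spacers)
  edges <- pairwise_similarity(cl)
  # nearly every pair overlaps when all isolates draw from one pool
  expect_gte(nrow(edges), 0.8 * choose(10, 2))
  expect_gt(median(edges$jaccard_binary), 0.15)
})

test_that("planted spacers are recovered at their recorded origins", {
  co <- simulate_cohort(n_isolates = 10, n_modules = 2, pool_size = 15,
                        seed = 21)
  org <- co$truth$spacer_origins
  org <- org[org$origin != "decoy", ]
  phages <- co$truth$phages
  for (i in sample(nrow(org), 20)) {
    ph <- phages$sequence[phages$phage_id == org$origin[i]]
    hits <- find_hits(org$sequence[i], ph,
                      max_mismatches = org$mismatches[i])
    match <- hits[hits$start == org$position[i] &
                    hits$strand == org$strand[i], ]
    expect_equal(nrow(match), 1)
    expect_equal(match$mismatches, org$mismatches[i])
  }
})

test_that("subject simulation plants targets inside the prophage interval", {
  sp <- setNames(replicate(10, rand_dna(32)), paste0("s", 1:10))
  set.seed(1)
  tg <- simulate_subjects(sp, n_subjects = 3, genome_length = 60000,
                          prophage_length = 20000, seed = 13)
  iv <- tg$truth$prophage_intervals
  tt <- tg$truth$targets
  expect_equal(nrow(iv), 3)
  for (s in iv$subject_id) {
    within <- tt[tt$subject_id == s, ]
    bounds <- iv[iv$subject_id == s, ]
    expect_true(all(within$start >= bounds$start &
                      within$end <= bounds$end))
  }
  # planted targets really occur in the emitted sequences
  one <- tt[1, ]
  seq <- tg$subjects[[one$subject_id]]
  window <- substr(seq, one$start, one$end)
  spacer <- unname(sp[one$spacer_id])
  if (one$strand == "-") window <- revcomp(window)
  expect_identical(window, spacer)
})

test_that("FASTA output of simulated records is byte-stable under a seed", {
  co1 <- simulate_cohort(n_isolates = 5, n_modules = 1, pool_size = 10,
                         seed = 3)
  co2 <- simulate_cohort(n_isolates = 5, n_modules = 1, pool_size = 10,
                         seed = 3)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(setNames(co1$spacers$sequence, co1$spacers$spacer_id), f1)
  write_fasta(setNames(co2$spacers$sequence, co2$spacers$spacer_id), f2)
  expect_identical(readLines(f1), readLines(f2))
})
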