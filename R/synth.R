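# Synthetic genomes, prophages, arrays, and cohorts with ground truth --------

#' Simulate a random genome sequence
#'
#' I.i.d. nucleotides with the requested expected GC fraction. Deterministic
#' under `seed`.
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc Expected GC fraction in `[0, 1]` (default 0.5).
#' @param seed Optional integer seed.
#' @return A single DNA string over `ACGT`.
#' @export
#' @examples
#' simulate_genome(20, gc = 0, seed = 1)
simulate_genome <- function(length, gc = 0.5, seed = NULL) {
  if (!is.numeric(length) || length < 1) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  if (gc < 0 || gc > 1) stop("`gc` must be in [0, 1]", call. = FALSE)
  with_seed_if(seed, {
    paste(sample(dna_alphabet, as.integer(length), replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
}

#' Implant a prophage into a genome
#'
#' Writes the prophage sequence into the genome. With `mode = "replace"`
#' (default) the genome slice at `position` is overwritten, which keeps all
#' other coordinates stable for truth bookkeeping; `mode = "insert"` splices
#' the prophage in, lengthening the genome.
#'
#' @param genome,prophage DNA strings.
#' @param position 1-based offset of the first prophage base.
#' @param mode `"replace"` or `"insert"`.
#' @return `list(sequence, interval)` where `interval` is the 1-based
#'   inclusive `(start, end)` of the implanted prophage.
#' @export
#' @examples
#' implant_prophage(strrep("A", 20), "CCCC", 5)$interval
implant_prophage <- function(genome, prophage, position,
                             mode = c("replace", "insert")) {
  mode <- match.arg(mode)
  genome <- check_seq(genome, "genome")
  prophage <- check_seq(prophage, "prophage")
  ng <- nchar(genome)
  np <- nchar(prophage)
  position <- as.integer(position)
  if (position < 1L) stop("`position` must be >= 1", call. = FALSE)
  if (mode == "replace") {
    if (position + np - 1L > ng) {
      stop("implant interval out of genome bounds", call. = FALSE)
    }
    seq <- paste0(substr(genome, 1L, position - 1L), prophage,
                  substr(genome, position + np, ng))
  } else {
    if (position > ng + 1L) {
      stop("implant interval out of genome bounds", call. = FALSE)
    }
    seq <- paste0(substr(genome, 1L, position - 1L), prophage,
                  substr(genome, position, ng))
  }
  list(sequence = seq, interval = c(start = position,
                                    end = position + np - 1L))
}

#' Implant a CRISPR array into a genome
#'
#' Inserts the canonical repeat-spacer cassette
#' `R . S1 . R . S2 ... R` (n spacers, n + 1 repeats) at `position`.
#'
#' @param genome DNA string.
#' @param repeat_seq Repeat sequence.
#' @param spacers Ordered character vector of spacer sequences (>= 1).
#' @param position 1-based offset; same semantics as [implant_prophage()].
#' @param mode `"replace"` or `"insert"`.
#' @return `list(sequence, interval, cassette)`.
#' @export
implant_crispr_array <- function(genome, repeat_seq, spacers, position,
                                 mode = c("replace", "insert")) {
  if (length(spacers) == 0L) {
    stop("`spacers` must contain at least one spacer", call. = FALSE)
  }
  repeat_seq <- check_seq(repeat_seq, "repeat_seq")
  cassette <- paste0(repeat_seq,
                     paste0(toupper(spacers), repeat_seq, collapse = ""))
  out <- implant_prophage(genome, cassette, position, mode)
  out$cassette <- cassette
  out
}

# plant k substitutions into a sequence (never an indel); returns the
# mutated string
plant_substitutions <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(dna_alphabet, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a CRISPR array cohort with latent module structure
#'
#' Emulates a collection of isolates whose arrays draw spacers from
#' module-specific pools. Each latent module owns a simulated phage genome;
#' its spacer pool is sampled from that phage on a jittered grid of positions
#' (protospacers spread along the phage), each spacer carrying a number of
#' planted substitutions drawn from `mismatch_profile`. Isolates are assigned
#' to modules in balanced fashion and draw their spacers without replacement
#' from their module's pool; a fraction of each isolate's spacers are private
#' decoys (random sequences with no planted origin).
#'
#' @param n_isolates Number of isolates (default 50).
#' @param n_modules Number of latent modules (default 5; must be
#'   <= `n_isolates`).
#' @param pool_size Spacers per module pool (default 40).
#' @param spacers_per_isolate Length-2 integer range; per-isolate spacer
#'   counts are uniform on it (default `c(6, 16)`, mean ~11 spacers per
#'   array).
#' @param decoy_fraction Expected fraction of decoy spacers per isolate
#'   (default 0.1).
#' @param mismatch_profile Probabilities of planting 0..4 substitutions in a
#'   pool spacer relative to its protospacer (default
#'   `c(0.6, 0.2, 0.1, 0.05, 0.05)`).
#' @param spacer_length Spacer length in nt (default 32).
#' @param phage_length Module phage length in bp (default 40000).
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#' @return A list of class `spacer_cohort`: `spacers` (tibble `isolate_id`,
#'   `spacer_index`, `spacer_id`, `sequence`) and `truth` (list with
#'   `module_labels`, `spacer_origins`, `phages`, `params`).
#' @export
simulate_cohort <- function(n_isolates = 50, n_modules = 5, pool_size = 40,
                            spacers_per_isolate = c(6, 16),
                            decoy_fraction = 0.1,
                            mismatch_profile = c(0.6, 0.2, 0.1, 0.05, 0.05),
                            spacer_length = 32, phage_length = 40000,
                            seed = NULL) {
  if (n_modules > n_isolates) {
    stop("`n_modules` must not exceed `n_isolates`", call. = FALSE)
  }
  if (spacers_per_isolate[1] > spacers_per_isolate[2] ||
      spacers_per_isolate[1] < 1) {
    stop("invalid `spacers_per_isolate` range", call. = FALSE)
  }
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    stop("`decoy_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (length(mismatch_profile) != 5L || any(mismatch_profile < 0)) {
    stop("`mismatch_profile` must be 5 non-negative weights for 0..4",
         call. = FALSE)
  }
  with_seed_if(seed, {
    phages <- tibble(
      phage_id = sprintf("phage_M%d", seq_len(n_modules)),
      module = seq_len(n_modules),
      sequence = vapply(seq_len(n_modules), function(i)
        simulate_genome(phage_length, 0.5), character(1))
    )
    pools <- purrr::map(seq_len(n_modules), function(mod) {
      bin <- (phage_length - spacer_length) %/% pool_size
      starts <- (seq_len(pool_size) - 1L) * bin +
        sample.int(max(1L, bin), pool_size, replace = TRUE)
      strands <- sample(c("+", "-"), pool_size, replace = TRUE)
      ks <- sample(0:4, pool_size, replace = TRUE, prob = mismatch_profile)
      proto <- substring(phages$sequence[mod], starts,
                         starts + spacer_length - 1L)
      spacer <- vapply(seq_len(pool_size), function(i) {
        s <- if (strands[i] == "-") revcomp(proto[i]) else proto[i]
        plant_substitutions(s, ks[i])
      }, character(1))
      tibble(
        spacer_id = sprintf("M%d_S%03d", mod, seq_len(pool_size)),
        sequence = spacer,
        origin = phages$phage_id[mod],
        position = starts,
        strand = strands,
        mismatches = ks
      )
    })
    module_of <- sample(rep(seq_len(n_modules), length.out = n_isolates))
    iso_ids <- sprintf("iso%03d", seq_len(n_isolates))
    decoy_counter <- 0L
    rows <- purrr::map(seq_len(n_isolates), function(i) {
      pool <- pools[[module_of[i]]]
      n_sp <- sample_range(spacers_per_isolate[1],
                           min(spacers_per_isolate[2], pool_size))
      n_decoy <- stats::rbinom(1, n_sp, decoy_fraction)
      n_pool <- n_sp - n_decoy
      drawn <- pool[sample(nrow(pool), n_pool), c("spacer_id", "sequence")]
      if (n_decoy > 0L) {
        decoys <- tibble(
          spacer_id = sprintf("%s_D%02d", iso_ids[i], seq_len(n_decoy)),
          sequence = vapply(seq_len(n_decoy), function(d)
            simulate_genome(spacer_length, 0.5), character(1))
        )
        drawn <- bind_rows(drawn, decoys)
      }
      drawn <- drawn[sample(nrow(drawn)), ]
      drawn$isolate_id <- iso_ids[i]
      drawn$spacer_index <- seq_len(nrow(drawn))
      drawn
    })
    spacers <- bind_rows(rows) |>
      select("isolate_id", "spacer_index", "spacer_id", "sequence")
    origins <- bind_rows(pools)
    decoy_ids <- setdiff(unique(spacers$spacer_id), origins$spacer_id)
    origins <- bind_rows(
      origins,
      tibble(spacer_id = decoy_ids,
             sequence = spacers$sequence[match(decoy_ids, spacers$spacer_id)],
             origin = "decoy", position = NA_integer_,
             strand = NA_character_, mismatches = NA_integer_)
    )
    truth <- list(
      module_labels = tibble(isolate_id = iso_ids, module = module_of),
      spacer_origins = origins,
      phages = phages,
      params = list(
        n_isolates = n_isolates, n_modules = n_modules,
        pool_size = pool_size, spacers_per_isolate = spacers_per_isolate,
        decoy_fraction = decoy_fraction,
        mismatch_profile = mismatch_profile,
        spacer_length = spacer_length, phage_length = phage_length
      )
    )
    structure(list(spacers = spacers, truth = truth),
              class = "spacer_cohort")
  })
}

#' @export
print.spacer_cohort <- function(x, ...) {
  p <- x$truth$params
  cat("<spacer_cohort> ", p$n_isolates, " isolates, ", p$n_modules,
      " latent modules, ", nrow(x$spacers), " spacers\n", sep = "")
  invisible(x)
}

#' Simulate subject genomes with implanted prophages and planted targets
#'
#' Builds genomes that carry one prophage each (a simulated phage implanted
#' at a random position) with a controlled number of protospacers planted
#' inside the prophage, on a jittered grid so the targets spread along it.
#' Each protospacer is the (optionally substituted) sequence of one of the
#' supplied spacers, written into the genome on a random strand. With
#' `scatter = TRUE` no prophage is implanted and the same number of targets
#' is planted uniformly across the whole genome instead - the negative
#' control for the MAD-based clustering test.
#'
#' @param spacers Named character vector of spacer sequences, or tibble with
#'   `spacer_id`/`sequence`.
#' @param n_subjects Number of genomes (default 10).
#' @param genome_length Genome length in bp (default 200000).
#' @param prophage_length Prophage length in bp (default 40000).
#' @param targets_per_subject Length-2 range for planted target counts
#'   (default `c(10, 15)`).
#' @param mismatch_profile Probabilities of 0..4 planted substitutions per
#'   target (default exact copies).
#' @param scatter Plant targets uniformly across the genome instead of
#'   inside a prophage (default `FALSE`).
#' @param seed Optional integer seed.
#' @return List of class `target_genomes`: `subjects` (named character
#'   vector), `truth` (list with `prophage_intervals`, `targets` tibbles).
#' @export
simulate_subjects <- function(spacers, n_subjects = 10,
                              genome_length = 200000,
                              prophage_length = 40000,
                              targets_per_subject = c(10, 15),
                              mismatch_profile = c(1, 0, 0, 0, 0),
                              scatter = FALSE, seed = NULL) {
  sp <- as_seq_tbl(spacers, "spacer_id")
  if (nrow(sp) == 0L) stop("need at least one spacer", call. = FALSE)
  spacer_length <- nchar(sp$sequence[1])
  if (!scatter && prophage_length >= genome_length) {
    stop("`prophage_length` must be smaller than `genome_length`",
         call. = FALSE)
  }
  with_seed_if(seed, {
    intervals <- list()
    targets <- list()
    subjects <- character(n_subjects)
    ids <- sprintf("genome%03d", seq_len(n_subjects))
    for (i in seq_len(n_subjects)) {
      g <- simulate_genome(genome_length, 0.5)
      n_t <- sample_range(targets_per_subject[1], targets_per_subject[2])
      if (scatter) {
        region_start <- 1L
        region_len <- genome_length
      } else {
        pos <- sample.int(genome_length - prophage_length + 1L, 1)
        ph <- simulate_genome(prophage_length, 0.5)
        imp <- implant_prophage(g, ph, pos)
        g <- imp$sequence
        intervals[[i]] <- tibble(subject_id = ids[i],
                                 start = unname(imp$interval[1]),
                                 end = unname(imp$interval[2]))
        region_start <- pos
        region_len <- prophage_length
      }
      # jittered grid keeps planted targets spread over the region
      bin <- (region_len - spacer_length) %/% n_t
      t_starts <- region_start + (seq_len(n_t) - 1L) * bin +
        sample.int(max(1L, bin), n_t, replace = TRUE) - 1L
      pick <- sample(nrow(sp), n_t, replace = nrow(sp) < n_t)
      strands <- sample(c("+", "-"), n_t, replace = TRUE)
      ks <- sample(0:4, n_t, replace = TRUE, prob = mismatch_profile)
      for (j in seq_len(n_t)) {
        proto <- plant_substitutions(sp$sequence[pick[j]], ks[j])
        if (strands[j] == "-") proto <- revcomp(proto)
        g <- implant_prophage(g, proto, t_starts[j])$sequence
      }
      targets[[i]] <- tibble(
        subject_id = ids[i],
        spacer_id = sp$spacer_id[pick],
        start = t_starts,
        end = t_starts + spacer_length - 1L,
        strand = strands,
        mismatches = ks
      )
      subjects[i] <- g
    }
    names(subjects) <- ids
    structure(
      list(subjects = subjects,
           truth = list(prophage_intervals = bind_rows(intervals),
                        targets = bind_rows(targets))),
      class = "target_genomes"
    )
  })
}

#' Construct a genome set exercising the self-targeting rules
#'
#' Builds one synthetic genome (chromosome + plasmid) whose CRISPR array
#' carries three kinds of spacers: array-only (no target elsewhere),
#' array + prophage (an exact protospacer planted inside a prophage region
#' of the chromosome), and array + plasmid (protospacer only on the
#' plasmid). The expected outcome - events for the array + prophage spacers
#' only, plasmid-only occurrences set aside - is returned as truth.
#'
#' @param n_array_only,n_prophage,n_plasmid Spacer counts per class
#'   (defaults 2, 2, 1).
#' @param chromosome_length,prophage_length,plasmid_length Sizes in bp.
#' @param repeat_seq Repeat sequence (default [crispr1_repeat]).
#' @param seed Optional integer seed.
#' @return List of class `selftarget_fixture`: `records` (tibble
#'   `record_id`, `role`, `sequence`), `truth` (tibble `spacer_seq`,
#'   `class`).
#' @export
simulate_selftarget_genome <- function(n_array_only = 2, n_prophage = 2,
                                       n_plasmid = 1,
                                       chromosome_length = 60000,
                                       prophage_length = 15000,
                                       plasmid_length = 8000,
                                       repeat_seq = crispr1_repeat,
                                       seed = NULL) {
  with_seed_if(seed, {
    n_sp <- n_array_only + n_prophage + n_plasmid
    spacers <- vapply(seq_len(n_sp), function(i) simulate_genome(32, 0.5),
                      character(1))
    classes <- c(rep("array-only", n_array_only),
                 rep("array+prophage", n_prophage),
                 rep("array+plasmid", n_plasmid))
    chrom <- simulate_genome(chromosome_length, 0.5)
    # array in the first quarter, prophage region in the last third
    arr <- implant_crispr_array(chrom, repeat_seq, spacers,
                                position = 2000)
    chrom <- arr$sequence
    pro_start <- chromosome_length - prophage_length - 2000L
    pro <- implant_prophage(chrom, simulate_genome(prophage_length, 0.5),
                            pro_start)
    chrom <- pro$sequence
    if (n_prophage > 0) {
      bin <- (prophage_length - 32L) %/% max(1L, n_prophage)
      for (j in seq_len(n_prophage)) {
        p <- pro_start + (j - 1L) * bin + sample.int(max(1L, bin - 32L), 1)
        chrom <- implant_prophage(chrom, spacers[n_array_only + j],
                                  p)$sequence
      }
    }
    plasmid <- simulate_genome(plasmid_length, 0.5)
    if (n_plasmid > 0) {
      for (j in seq_len(n_plasmid)) {
        p <- 500L + (j - 1L) * 1000L
        plasmid <- implant_prophage(plasmid,
                                    spacers[n_array_only + n_prophage + j],
                                    p)$sequence
      }
    }
    records <- tibble(
      record_id = c("chromosome", "plasmid1"),
      role = c("chromosome", "plasmid"),
      sequence = c(chrom, plasmid)
    )
    structure(
      list(records = records,
           truth = tibble(spacer_seq = spacers, class = classes,
                          prophage_interval = list(pro$interval))),
      class = "selftarget_fixture"
    )
  })
}
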