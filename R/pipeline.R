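# End-to-end pipeline --------------------------------------------------------

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its default:
#' repeat sequence, 4-mismatch/zero-gap spacer homology, 100-bp
#' repeat-proximity mask, 500 permutation replicates and the 95th-percentile
#' edge threshold, >= 10 targets and 25-kb flanks for prophage regions,
#' 95%/85% identity/coverage dedup, MCL inflation 2, and exact matching for
#' the self-targeting screen.
#'
#' @param repeat_seq Conserved repeat (default [crispr1_repeat]).
#' @param max_mismatches Protospacer homology tolerance (default 4).
#' @param mask_window Repeat-proximity mask in bp (default 100).
#' @param repeat_max_mismatches Repeat-location tolerance (default 3).
#' @param spacer_len_bounds Spacer length bounds (default `c(20, 50)`).
#' @param cluster_policy Spacer clustering policy (default
#'   `"exact-canonical"`).
#' @param index Similarity index for the network (default binary Jaccard).
#' @param null_replicates Permutation replicates (default 500).
#' @param null_percentile Threshold percentile (default 95).
#' @param module_method Community detection method (default
#'   `"greedy-modularity"`).
#' @param min_hits Minimum targets for a prophage region (default 10).
#' @param flank Region flank in bp (default 25000).
#' @param min_identity,min_coverage Dedup thresholds in percent (95, 85).
#' @param inflation MCL inflation (default 2).
#' @param selftarget_max_mismatches Stringency for "present elsewhere"
#'   (default 0).
#' @param seed Master seed; stage seeds are derived at fixed offsets.
#' @return A list of class `spacer_config`.
#' @export
spacer_config <- function(repeat_seq = crispr1_repeat,
                          max_mismatches = 4, mask_window = 100,
                          repeat_max_mismatches = 3,
                          spacer_len_bounds = c(20, 50),
                          cluster_policy = "exact-canonical",
                          index = "jaccard_binary",
                          null_replicates = 500, null_percentile = 95,
                          module_method = "greedy-modularity",
                          min_hits = 10, flank = 25000,
                          min_identity = 95, min_coverage = 85,
                          inflation = 2, selftarget_max_mismatches = 0,
                          seed = 1) {
  structure(
    list(repeat_seq = repeat_seq, max_mismatches = max_mismatches,
         mask_window = mask_window,
         repeat_max_mismatches = repeat_max_mismatches,
         spacer_len_bounds = spacer_len_bounds,
         cluster_policy = cluster_policy, index = index,
         null_replicates = null_replicates,
         null_percentile = null_percentile,
         module_method = module_method,
         min_hits = min_hits, flank = flank,
         min_identity = min_identity, min_coverage = min_coverage,
         inflation = inflation,
         selftarget_max_mismatches = selftarget_max_mismatches,
         seed = seed),
    class = "spacer_config"
  )
}

#' Run the end-to-end spacer analysis
#'
#' Composes the stages: array extraction -> spacer clustering and
#' known/new classification -> spacer-sharing network with permutation-null
#' threshold and module detection -> protospacer search with repeat masking
#' -> target summaries and prophage-region calling -> self-targeting
#' screen. Identical seeds and inputs give identical results.
#'
#' @param isolates Array-bearing sequences (named character vector, data
#'   frame with id/sequence, or FASTA path).
#' @param subjects Optional subject genomes to search for protospacers.
#' @param roles Optional tibble (`record_id`, `genome_id`, `role`) marking
#'   chromosome/plasmid records for the self-targeting screen; when absent,
#'   every subject is treated as a chromosome of its own genome.
#' @param reference Optional character vector of known spacer sequences.
#' @param config A [spacer_config()].
#' @return A list of class `spacer_run` with elements `spacers`,
#'   `clustered`, `clusters`, `edges`, `null`, `threshold`, `network`,
#'   `modules`, `hits`, `target_summary`, `regions`, `selftarget`,
#'   `positional`, and a `summary` of per-stage counts.
#' @export
run_pipeline <- function(isolates, subjects = NULL, roles = NULL,
                         reference = NULL, config = spacer_config()) {
  stopifnot(inherits(config, "spacer_config"))
  seed <- as.integer(config$seed)
  spacers <- extract_arrays(isolates, config$repeat_seq,
                            config$repeat_max_mismatches,
                            config$spacer_len_bounds)
  if (nrow(spacers) == 0L) {
    warning("no arrays extracted; returning empty run", call. = FALSE)
    return(structure(list(spacers = spacers, summary = list(n_spacers = 0L)),
                     class = "spacer_run"))
  }
  clustered <- cluster_spacers(spacers, config$cluster_policy)
  clusters <- classify_known_new(clustered,
                                 reference %||% character(0))
  positional <- NULL
  if (!is.null(reference)) {
    pos <- add_relative_positions(clustered) |>
      left_join(select(clusters, "cluster_id", "status"), by = "cluster_id")
    if (length(unique(pos$status)) == 2L) {
      positional <- positional_comparison(
        pos$rel_pos[pos$status == "known"],
        pos$rel_pos[pos$status == "new"]
      )
    }
  }
  null <- permutation_null(clustered, config$null_replicates,
                           config$index, seed = seed + 1L)
  threshold <- threshold_from_null(null, config$null_percentile)
  network <- build_network(clustered, config$index, threshold)
  modules <- detect_modules(network, config$module_method, seed = seed + 2L)
  hits <- NULL
  target_summary <- NULL
  regions <- NULL
  selftarget <- NULL
  if (!is.null(subjects)) {
    if (is.character(subjects) && length(subjects) == 1L &&
        is.null(names(subjects)) && file.exists(subjects)) {
      subjects <- read_fasta(subjects)
    }
    su <- as_seq_tbl(subjects, "subject_id")
    reps <- cluster_summary(clustered)
    hits <- scan_collection(reps, su, config$max_mismatches,
                            config$repeat_seq, config$mask_window,
                            config$repeat_max_mismatches)
    lens <- stats::setNames(nchar(su$sequence), su$subject_id)
    target_summary <- summarize_targets(hits, lens)
    regions <- call_regions(hits, lens, config$min_hits, config$flank)
    if (is.null(roles)) {
      roles <- tibble(record_id = su$subject_id,
                      genome_id = su$subject_id, role = "chromosome")
    }
    st <- purrr::map(unique(roles$genome_id), function(g) {
      recs <- roles[roles$genome_id == g, , drop = FALSE]
      recs$sequence <- su$sequence[match(recs$record_id, su$subject_id)]
      if (!any(recs$role == "chromosome")) return(NULL)
      scan <- detect_self_targeting(
        recs, config$repeat_seq, config$selftarget_max_mismatches,
        genome_id = g,
        repeat_max_mismatches = config$repeat_max_mismatches,
        spacer_len_bounds = config$spacer_len_bounds,
        window = config$mask_window)
      list(events = classify_events(scan$events, regions),
           plasmid_only = scan$plasmid_only)
    })
    st <- purrr::compact(st)
    selftarget <- list(
      events = bind_rows(purrr::map(st, "events")),
      plasmid_only = bind_rows(purrr::map(st, "plasmid_only"))
    )
  }
  summary <- list(
    n_isolates = dplyr::n_distinct(spacers$isolate_id),
    n_spacers = nrow(spacers),
    n_clusters = nrow(clusters),
    n_known = sum(clusters$status == "known"),
    n_new = sum(clusters$status == "new"),
    threshold = threshold,
    n_edges = igraph::ecount(network),
    n_modules = max(modules$module),
    n_hits = if (is.null(hits)) 0L else sum(!hits$masked),
    n_masked = if (is.null(hits)) 0L else sum(hits$masked),
    n_regions = if (is.null(regions)) 0L else nrow(regions),
    n_events = if (is.null(selftarget)) 0L else nrow(selftarget$events)
  )
  structure(
    list(spacers = spacers, clustered = clustered, clusters = clusters,
         edges = pairwise_similarity(clustered), null = null,
         threshold = threshold, network = network, modules = modules,
         hits = hits, target_summary = target_summary, regions = regions,
         selftarget = selftarget, positional = positional,
         config = config, summary = summary),
    class = "spacer_run"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spacer_run <- function(x, ...) {
  s <- x$summary
  cat("<spacer_run>\n")
  for (k in names(s)) {
    v <- s[[k]]
    cat(sprintf("  %-12s %s\n", k,
                if (is.numeric(v)) format(signif(v, 4)) else v))
  }
  invisible(x)
}
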