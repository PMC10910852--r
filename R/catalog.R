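# Spacer catalogue: deduplication and known/new classification ---------------

#' Cluster spacers by sequence identity
#'
#' Groups spacer records into clusters of identical sequences. Under the
#' default `"exact-canonical"` policy a sequence is identified with its
#' reverse complement (spacers read from opposite strands are the same
#' biological spacer); `"exact"` groups identical strings only. Cluster ids
#' are assigned by decreasing cluster size, ties broken by representative
#' sequence; the representative is the lexicographically smallest member.
#'
#' @param spacers Tibble with at least `spacer_id` and `sequence` columns
#'   (e.g. from [extract_arrays()] or [simulate_cohort()]).
#' @param policy `"exact-canonical"` (default) or `"exact"`.
#' @return The input tibble with `cluster_id` and `cluster_key` columns
#'   appended; every spacer id belongs to exactly one cluster.
#' @seealso [cluster_summary()], [classify_known_new()]
#' @export
cluster_spacers <- function(spacers, policy = c("exact-canonical", "exact")) {
  policy <- match.arg(policy)
  if (!is.data.frame(spacers) || nrow(spacers) == 0L) {
    stop("`spacers` must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("spacer_id", "sequence") %in% names(spacers)))
  seqs <- toupper(spacers$sequence)
  key <- if (policy == "exact-canonical") canonical_seq(seqs) else seqs
  sizes <- table(key)
  rep_by_key <- tapply(seqs, key, function(s) min(s))
  ord <- order(-as.integer(sizes[names(rep_by_key)]), rep_by_key)
  ranked <- names(rep_by_key)[ord]
  id_map <- stats::setNames(
    sprintf("SC%04d", seq_along(ranked)), ranked
  )
  out <- spacers
  out$cluster_key <- key
  out$cluster_id <- unname(id_map[key])
  attr(out, "policy") <- policy
  out
}

#' Summarise spacer clusters
#'
#' @param clustered Output of [cluster_spacers()].
#' @return One row per cluster: `cluster_id`, `representative` (smallest
#'   member sequence), `size`, and `n_isolates` when an `isolate_id` column
#'   is present. Sizes sum to the number of input spacers.
#' @export
cluster_summary <- function(clustered) {
  stopifnot("cluster_id" %in% names(clustered))
  grp <- clustered |>
    group_by(.data$cluster_id) |>
    summarise(
      representative = min(toupper(.data$sequence)),
      size = dplyr::n(),
      n_isolates = if ("isolate_id" %in% names(clustered))
        dplyr::n_distinct(.data$isolate_id) else NA_integer_,
      .groups = "drop"
    ) |>
    arrange(.data$cluster_id)
  grp
}

#' Classify spacer clusters as known or new
#'
#' A cluster is `"known"` when any member sequence (either strand) has an
#' exact, full-length match in the reference spacer set; otherwise it is
#' `"new"` (the 0-mismatch, 100%-coverage rule).
#'
#' @param clustered Output of [cluster_spacers()].
#' @param reference Character vector of reference spacer sequences (may be
#'   empty: everything is then new).
#' @return Cluster summary tibble with a `status` column (`known`/`new`).
#' @export
classify_known_new <- function(clustered, reference = character(0)) {
  reference <- toupper(reference)
  ref_all <- unique(c(reference, revcomp(reference)))
  per_cluster <- clustered |>
    group_by(.data$cluster_id) |>
    summarise(status = if (any(toupper(.data$sequence) %in% ref_all))
      "known" else "new", .groups = "drop")
  left_join(cluster_summary(clustered), per_cluster, by = "cluster_id")
}

#' Compare two positional distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of relative spacer positions
#' (e.g. known vs new spacers along the 5'->3' array axis), using the
#' asymptotic null distribution.
#'
#' @param group_a,group_b Numeric vectors of positions (fractions in
#'   `[0, 1]`), both non-empty.
#' @return A one-row tibble: `statistic` (D, the sup distance between the
#'   two empirical CDFs), `p_value`, `n_a`, `n_b`.
#' @export
#' @examples
#' positional_comparison(c(0.1, 0.2, 0.3), c(0.2, 0.4))
positional_comparison <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(group_a, group_b, exact = FALSE))
  tibble(
    statistic = unname(ks$statistic),
    p_value = unname(ks$p.value),
    n_a = length(group_a),
    n_b = length(group_b)
  )
}
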