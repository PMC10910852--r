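# Spacer-sharing network with permutation-null edge threshold ----------------

#' Similarity indices over spacer content
#'
#' `binary_jaccard()` compares two sets of spacer clusters
#' (`|A n B| / |A u B|`, 0 when both are empty). `weighted_jaccard()` and
#' `tanimoto()` compare per-cluster count vectors:
#' `sum(min) / sum(max)` and `a.b / (|a|^2 + |b|^2 - a.b)` respectively.
#' Count vectors may be named (aligned on the union of names) or unnamed and
#' equal-length. All three indices are symmetric, lie in `[0, 1]`, and equal
#' 1 on identical non-empty inputs.
#'
#' @param a,b Character vectors (sets) for `binary_jaccard()`; non-negative
#'   count vectors for the others.
#' @return A number in `[0, 1]`.
#' @name similarity-indices
NULL

#' @rdname similarity-indices
#' @export
#' @examples
#' binary_jaccard(c("a", "b", "c"), c("b", "c", "d"))
binary_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

align_counts <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    keys <- union(names(a), names(b))
    a <- stats::setNames(a[keys], keys)
    b <- stats::setNames(b[keys], keys)
    a[is.na(a)] <- 0
    b[is.na(b)] <- 0
  } else if (length(a) != length(b)) {
    stop("unnamed count vectors must have equal length", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  list(a = as.numeric(a), b = as.numeric(b))
}

#' @rdname similarity-indices
#' @export
weighted_jaccard <- function(a, b) {
  v <- align_counts(a, b)
  denom <- sum(pmax(v$a, v$b))
  if (denom == 0) return(0)
  sum(pmin(v$a, v$b)) / denom
}

#' @rdname similarity-indices
#' @export
tanimoto <- function(a, b) {
  v <- align_counts(a, b)
  ab <- sum(v$a * v$b)
  denom <- sum(v$a^2) + sum(v$b^2) - ab
  if (denom == 0) stop("tanimoto undefined for two zero vectors",
                       call. = FALSE)
  ab / denom
}

# isolate x cluster count matrix from a clustered spacer table
spacer_count_matrix <- function(clustered) {
  stopifnot(all(c("isolate_id", "cluster_id") %in% names(clustered)))
  iso <- factor(clustered$isolate_id)
  cl <- factor(clustered$cluster_id)
  X <- matrix(0L, nlevels(iso), nlevels(cl),
              dimnames = list(levels(iso), levels(cl)))
  X[] <- tabulate(as.integer(iso) + (as.integer(cl) - 1L) * nlevels(iso),
                  nbins = nlevels(iso) * nlevels(cl))
  X
}

# all three indices for every isolate pair sharing >= 1 spacer cluster,
# computed with matrix algebra (Manhattan-distance identity for the
# weighted Jaccard: sum(min) = (ra + rb - |a - b|_1) / 2)
pairwise_from_matrix <- function(X) {
  B <- X > 0
  S <- tcrossprod(B * 1L)
  rb <- rowSums(B)
  U <- outer(rb, rb, "+") - S
  JB <- ifelse(U > 0, S / U, 0)
  ra <- rowSums(X)
  D1 <- as.matrix(stats::dist(X, method = "manhattan"))
  RA <- outer(ra, ra, "+")
  JW <- ifelse(RA + D1 > 0, (RA - D1) / (RA + D1), 0)
  XX <- tcrossprod(X)
  nrm <- rowSums(X^2)
  TD <- outer(nrm, nrm, "+") - XX
  TAN <- ifelse(TD > 0, XX / TD, 0)
  idx <- which(upper.tri(S) & S >= 1L, arr.ind = TRUE)
  tibble(
    isolate_a = rownames(X)[idx[, 1]],
    isolate_b = rownames(X)[idx[, 2]],
    shared_count = S[idx],
    jaccard_binary = JB[idx],
    jaccard_weighted = JW[idx],
    tanimoto = TAN[idx]
  )
}

#' Pairwise spacer-sharing similarity between isolates
#'
#' Links any two isolates sharing at least one spacer cluster and reports
#' the three similarity indices for each such pair.
#'
#' @param clustered Clustered spacer tibble from [cluster_spacers()] (needs
#'   `isolate_id` and `cluster_id` columns).
#' @return Edge tibble: `isolate_a`, `isolate_b`, `shared_count` (distinct
#'   shared clusters), `jaccard_binary`, `jaccard_weighted`, `tanimoto`.
#' @export
pairwise_similarity <- function(clustered) {
  X <- spacer_count_matrix(clustered)
  if (nrow(X) < 2L) {
    return(tibble(isolate_a = character(0), isolate_b = character(0),
                  shared_count = integer(0), jaccard_binary = numeric(0),
                  jaccard_weighted = numeric(0), tanimoto = numeric(0)))
  }
  pairwise_from_matrix(X)
}

#' Permutation null for spacer-sharing similarity
#'
#' Builds the null distribution of pairwise similarity used to calibrate the
#' edge threshold: in each replicate the global spacer multiset is randomly
#' redistributed among isolates, with each isolate keeping its original
#' spacer count (a random permutation of the pooled spacers, partitioned by
#' the original counts). Similarity values for all pairs sharing at least
#' one spacer are pooled across pairs and replicates.
#'
#' @param clustered Clustered spacer tibble ([cluster_spacers()]).
#' @param n_replicates Number of random datasets (default 500).
#' @param index Which similarity index to pool (default binary Jaccard).
#' @param seed Optional integer seed; identical seeds give identical nulls.
#' @param keep_replicates Keep each replicate's isolate/cluster assignment
#'   (as a list of integer vectors) for conservation checks.
#' @return An object of class `spacer_null`: pooled `values`,
#'   `n_replicates`, `index`, per-isolate `counts`, and optionally
#'   `replicates`.
#' @seealso [threshold_from_null()]
#' @export
permutation_null <- function(clustered, n_replicates = 500,
                             index = c("jaccard_binary", "jaccard_weighted",
                                       "tanimoto"),
                             seed = NULL, keep_replicates = FALSE) {
  index <- match.arg(index)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  iso <- factor(clustered$isolate_id)
  if (nlevels(iso) < 2L) stop("need at least 2 isolates", call. = FALSE)
  cl <- as.integer(factor(clustered$cluster_id))
  n_iso <- nlevels(iso)
  n_cl <- max(cl)
  iso_i <- as.integer(iso)
  reps <- if (keep_replicates) vector("list", n_replicates) else NULL
  values <- with_seed_if(seed, {
    purrr::map(seq_len(n_replicates), function(r) {
      perm <- sample(cl)
      if (keep_replicates) reps[[r]] <<- perm
      X <- matrix(0L, n_iso, n_cl)
      X[] <- tabulate(iso_i + (perm - 1L) * n_iso, nbins = n_iso * n_cl)
      rownames(X) <- levels(iso)
      edges <- pairwise_from_matrix(X)
      edges[[index]]
    })
  })
  structure(
    list(
      values = unlist(values),
      n_replicates = as.integer(n_replicates),
      index = index,
      counts = tabulate(iso_i, n_iso),
      isolates = levels(iso),
      replicates = reps,
      original_assignment = list(isolate = iso_i, cluster = cl)
    ),
    class = "spacer_null"
  )
}

#' @export
print.spacer_null <- function(x, ...) {
  cat("<spacer_null> ", x$n_replicates, " replicates, index = ", x$index,
      "\n  ", length(x$values), " pooled pair values; 95th percentile = ",
      signif(threshold_from_null(x, 95), 3), "\n", sep = "")
  invisible(x)
}

#' Edge threshold from a permutation null
#'
#' Nearest-rank empirical percentile of the pooled null similarity values:
#' the value under which `percentile`% of null pair similarities fall.
#' Monotone non-decreasing in `percentile`.
#'
#' @param dist A `spacer_null` object or a numeric vector of pooled values.
#' @param percentile Percentile in (0, 100] (default 95).
#' @return The threshold value.
#' @export
threshold_from_null <- function(dist, percentile = 95) {
  v <- if (inherits(dist, "spacer_null")) dist$values else as.numeric(dist)
  if (length(v) == 0L) stop("empty null distribution", call. = FALSE)
  if (percentile <= 0 || percentile > 100) {
    stop("`percentile` must be in (0, 100]", call. = FALSE)
  }
  v <- sort(v)
  k <- max(1L, ceiling(percentile / 100 * length(v)))
  v[k]
}

#' Build the spacer-sharing network
#'
#' Nodes are all isolates (isolated nodes included); an edge joins two
#' isolates when they share at least one spacer cluster and their similarity
#' is at or above the threshold (the boundary is kept: only connections
#' strictly below the threshold are removed).
#'
#' @param clustered Clustered spacer tibble.
#' @param index Similarity index used for thresholding.
#' @param threshold Edge threshold in `[0, 1]` (e.g. from
#'   [threshold_from_null()]).
#' @return An undirected `igraph` graph; edges carry `weight` (the index
#'   value) and `shared_count`.
#' @export
build_network <- function(clustered, index = c("jaccard_binary",
                                               "jaccard_weighted",
                                               "tanimoto"),
                          threshold = 0) {
  index <- match.arg(index)
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  edges <- pairwise_similarity(clustered)
  edges <- edges[edges[[index]] >= threshold, , drop = FALSE]
  isolates <- sort(unique(clustered$isolate_id))
  el <- tibble(from = edges$isolate_a, to = edges$isolate_b,
               weight = edges[[index]], shared_count = edges$shared_count)
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = tibble(name = isolates))
}

#' Detect modules in the spacer-sharing network
#'
#' Community detection over the thresholded network. The default greedy
#' modularity optimisation is deterministic; label propagation is stochastic
#' and is run under the supplied seed; connected components are the coarsest
#' choice. Isolated nodes always become singleton modules. Modules are
#' renumbered by decreasing size.
#'
#' @param graph Network from [build_network()].
#' @param method One of `"greedy-modularity"` (default),
#'   `"label-propagation"`, `"connected-components"`.
#' @param seed Seed for stochastic methods (default 1).
#' @return A tibble of class `module_partition`: `isolate_id`, `module`
#'   (integer). Attribute `method`.
#' @export
detect_modules <- function(graph, method = c("greedy-modularity",
                                             "label-propagation",
                                             "connected-components"),
                           seed = 1) {
  method <- match.arg(method)
  memb <- switch(
    method,
    "greedy-modularity" = igraph::membership(igraph::cluster_fast_greedy(graph)),
    "label-propagation" = with_seed_if(
      seed, igraph::membership(igraph::cluster_label_prop(graph))),
    "connected-components" = igraph::components(graph)$membership
  )
  sizes <- sort(table(memb), decreasing = TRUE)
  renum <- stats::setNames(seq_along(sizes), names(sizes))
  out <- tibble(
    isolate_id = names(memb),
    module = unname(renum[as.character(memb)])
  ) |>
    arrange(.data$module, .data$isolate_id)
  structure(out, method = method,
            class = c("module_partition", class(out)))
}
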