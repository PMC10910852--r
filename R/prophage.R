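# Prophage calling, viral dedup, and Markov clustering -----------------------

#' Unscaled median absolute deviation of target positions
#'
#' `median(|x - median(x)|)` without the normal-consistency constant: a pure
#' dispersion proxy. Low values mean targets condensed around the median
#' (prophage-like clustering); high values mean targets scattered across the
#' genome.
#'
#' @param positions Numeric vector of hit positions (>= 1 value; callers
#'   apply it to subjects with >= 2 hits).
#' @return The unscaled MAD (0 for a single position).
#' @export
#' @examples
#' position_mad(c(10, 12, 14))
position_mad <- function(positions) {
  if (length(positions) == 0L) stop("empty position vector", call. = FALSE)
  stats::mad(positions, constant = 1)
}

#' Per-subject target summary
#'
#' Counts unmasked hits per subject and measures the unscaled MAD of their
#' start positions (only for subjects with at least two hits). This is the
#' statistic behind the targets-vs-MAD scatter used to separate
#' prophage-bearing genomes from scattered-target genomes.
#'
#' @param hits Hit tibble (e.g. from [scan_collection()]); masked hits are
#'   excluded.
#' @param subject_lengths Optional named vector of subject lengths.
#' @return Tibble of class `target_summary`: `subject_id`, `n_hits`, `mad`
#'   (`NA` when `n_hits < 2`), `first_start`, `last_end`, `subject_length`.
#' @export
summarize_targets <- function(hits, subject_lengths = NULL) {
  h <- hits[!hits$masked, , drop = FALSE]
  out <- h |>
    group_by(.data$subject_id) |>
    summarise(
      n_hits = dplyr::n(),
      mad = if (dplyr::n() >= 2L) position_mad(.data$start) else NA_real_,
      first_start = min(.data$start),
      last_end = max(.data$end),
      .groups = "drop"
    )
  out$subject_length <- if (is.null(subject_lengths)) NA_integer_ else
    unname(subject_lengths[out$subject_id])
  structure(out, class = c("target_summary", class(out)))
}

#' Call candidate prophage regions from clustered targets
#'
#' For every subject with at least `min_hits` unmasked hits, the candidate
#' prophage region spans the minimum hit start to the maximum hit end,
#' extended by `flank` bp on each side and clipped to the subject bounds.
#' One region per subject; multi-prophage genomes yield one merged span.
#'
#' @param hits Hit tibble; masked hits are ignored.
#' @param subject_lengths Named vector of subject lengths (for clipping).
#' @param min_hits Minimum number of targets (default 10).
#' @param flank Flank in bp added on each side (default 25000).
#' @return Tibble: `subject_id`, `start`, `end`, `n_support`, `flank`.
#'   Subjects below `min_hits` yield no row.
#' @export
call_regions <- function(hits, subject_lengths, min_hits = 10,
                         flank = 25000) {
  if (flank < 0) stop("`flank` must be non-negative", call. = FALSE)
  h <- hits[!hits$masked, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(tibble(subject_id = character(0), start = integer(0),
                  end = integer(0), n_support = integer(0),
                  flank = integer(0)))
  }
  h |>
    group_by(.data$subject_id) |>
    summarise(n_support = dplyr::n(),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    filter(.data$n_support >= min_hits) |>
    mutate(
      start = pmax(1L, as.integer(.data$start - flank)),
      end = pmin(as.integer(unname(subject_lengths[.data$subject_id])),
                 as.integer(.data$end + flank)),
      flank = as.integer(flank)
    ) |>
    select("subject_id", "start", "end", "n_support", "flank")
}

# k-mer anchored gapless identity between two sequences; both orientations
# of b are tried. Returns matched/aligned column counts for the best chain.
anchor_chain <- function(a, b, k) {
  na <- nchar(a)
  nb <- nchar(b)
  if (min(na, nb) < 2L * k) {
    # tiny sequences: best single diagonal by exhaustive shift
    best <- c(matches = 0, cols = 0)
    for (d in seq(-(nb - 1L), na - 1L)) {
      as <- max(1L, 1L + d)
      ae <- min(na, nb + d)
      if (ae < as) next
      cols <- ae - as + 1L
      m <- sum(charToRaw(substr(a, as, ae)) ==
                 charToRaw(substr(b, as - d, ae - d)))
      if (m > best["matches"]) best <- c(matches = m, cols = cols)
    }
    return(best)
  }
  starts_b <- seq_len(nb - k + 1L)
  kmers_b <- substring(b, starts_b, starts_b + k - 1L)
  index_b <- split(starts_b, kmers_b)
  starts_a <- seq_len(na - k + 1L)
  kmers_a <- substring(a, starts_a, starts_a + k - 1L)
  hit <- kmers_a %in% names(index_b)
  if (!any(hit)) return(c(matches = 0, cols = 0))
  pos_b <- index_b[kmers_a[hit]]
  n_each <- lengths(pos_b)
  keep <- n_each <= 100L  # cap pathological repeats
  ai <- rep(starts_a[hit][keep], n_each[keep])
  bj <- unlist(pos_b[keep], use.names = FALSE)
  diag <- ai - bj
  tab <- sort(table(diag), decreasing = TRUE)
  cand <- as.integer(names(tab)[tab >= 3L])
  if (length(cand) == 0L) cand <- as.integer(names(tab)[1])
  cand <- utils::head(cand, 30L)
  segs <- purrr::map(cand, function(d) {
    sel <- diag == d
    as <- min(ai[sel])
    ae <- max(ai[sel]) + k - 1L
    bs <- as - d
    be <- ae - d
    cols <- ae - as + 1L
    m <- sum(charToRaw(substr(a, as, ae)) == charToRaw(substr(b, bs, be)))
    list(astart = as, aend = ae, bstart = bs, bend = be,
         matches = m, cols = cols)
  })
  # greedy chain: best segments first, no overlap in either sequence
  ord <- order(-vapply(segs, `[[`, numeric(1), "matches"))
  acc <- list()
  for (i in ord) {
    s <- segs[[i]]
    clash <- any(vapply(acc, function(t) {
      (s$astart <= t$aend && s$aend >= t$astart) ||
        (s$bstart <= t$bend && s$bend >= t$bstart)
    }, logical(1)))
    if (!clash) acc <- c(acc, list(s))
  }
  c(matches = sum(vapply(acc, `[[`, numeric(1), "matches")),
    cols = sum(vapply(acc, `[[`, numeric(1), "cols")))
}

#' Gapless percent identity and coverage between two sequences
#'
#' Anchors shared k-mers, groups them by diagonal, extends each diagonal to
#' a gapless segment, and chains non-overlapping segments greedily. Identity
#' is matched columns over aligned columns of the chain; coverage is aligned
#' columns over the length of the shorter sequence (so full containment of
#' the shorter sequence scores coverage 100). Both orientations of `b` are
#' tried and the better one reported. Symmetric by construction (arguments
#' are ordered internally).
#'
#' @param a,b DNA strings (non-empty).
#' @param k Anchor k-mer size (default 13).
#' @return One-row tibble: `identity` and `coverage` in percent, `strand`
#'   of the better orientation.
#' @export
pairwise_identity <- function(a, b, k = 13) {
  a <- check_seq(a, "a")
  b <- check_seq(b, "b")
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  fwd <- anchor_chain(a, b, k)
  rev <- anchor_chain(a, revcomp(b), k)
  use_rev <- rev["matches"] > fwd["matches"]
  best <- if (use_rev) rev else fwd
  shorter <- min(nchar(a), nchar(b))
  tibble(
    identity = if (best[["cols"]] > 0)
      100 * best[["matches"]] / best[["cols"]] else 0,
    coverage = 100 * best[["cols"]] / shorter,
    strand = if (use_rev) "-" else "+"
  )
}

#' Deduplication graph over viral sequences
#'
#' Nodes are sequences; an undirected edge joins two sequences deemed
#' identical at the species level: at least `min_identity`% identity over at
#' least `min_coverage`% coverage (of the shorter sequence).
#'
#' @param sequences Named character vector or data frame with id/sequence.
#' @param min_identity,min_coverage Thresholds in percent (defaults 95 and
#'   85).
#' @param k Anchor k-mer size passed to [pairwise_identity()].
#' @return An `igraph` graph over all sequences; edges carry `identity` and
#'   `coverage`.
#' @export
dedup_graph <- function(sequences, min_identity = 95, min_coverage = 85,
                        k = 13) {
  tbl <- as_seq_tbl(sequences, "seq_id")
  if (nrow(tbl) == 0L) stop("need at least one sequence", call. = FALSE)
  edges <- NULL
  if (nrow(tbl) >= 2L) {
    pairs <- utils::combn(nrow(tbl), 2)
    edges <- purrr::map(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]
      j <- pairs[2, p]
      pi <- pairwise_identity(tbl$sequence[i], tbl$sequence[j], k)
      if (pi$identity >= min_identity && pi$coverage >= min_coverage) {
        tibble(from = tbl$seq_id[i], to = tbl$seq_id[j],
               identity = pi$identity, coverage = pi$coverage)
      } else NULL
    })
    edges <- bind_rows(edges)
  }
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(from = character(0), to = character(0),
                    identity = numeric(0), coverage = numeric(0))
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = tibble(name = tbl$seq_id))
}

#' Markov clustering (MCL)
#'
#' From-scratch MCL over an undirected (weighted) graph: self-loops of
#' weight 1 are added, the adjacency matrix is column-normalised to a
#' transition matrix, then expansion (matrix squaring) alternates with
#' inflation (elementwise power `inflation` followed by column
#' renormalisation) and pruning of entries below `tol`, until the maximum
#' elementwise change falls below `tol` or `max_iter` is reached. Clusters
#' are read from the connected structure of the limit matrix, so nodes from
#' different connected components are never merged. One member per cluster
#' is kept as representative: the longest (when lengths are supplied), ties
#' broken by smallest id.
#'
#' @param graph An `igraph` graph or a symmetric adjacency matrix.
#' @param inflation Inflation exponent (> 1; default 2).
#' @param max_iter Iteration cap (default 100).
#' @param tol Pruning/convergence tolerance (default 1e-6).
#' @param seq_lengths Optional named vector of member sequence lengths used
#'   to pick representatives.
#' @return Tibble of class `mcl_partition`: `id`, `cluster` (integer,
#'   numbered by decreasing size), `representative`. Attributes
#'   `iterations`, `converged`, `inflation`.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100, tol = 1e-6,
                        seq_lengths = NULL) {
  if (inflation <= 1) stop("`inflation` must be > 1", call. = FALSE)
  if (inherits(graph, "igraph")) {
    A <- igraph::as_adjacency_matrix(
      graph, sparse = FALSE,
      attr = if ("weight" %in% igraph::edge_attr_names(graph)) "weight"
             else NULL)
  } else {
    A <- as.matrix(graph)
  }
  n <- nrow(A)
  if (n == 0L) stop("empty graph", call. = FALSE)
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- paste0("v", seq_len(n))
  }
  diag(A) <- diag(A) + 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mx <- M %*% M
    Mx <- Mx^inflation
    Mx[Mx < tol] <- 0
    cs <- colSums(Mx)
    cs[cs == 0] <- 1
    Mx <- sweep(Mx, 2, cs, "/")
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  P <- (M > 0) | t(M > 0)
  g2 <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                            diag = FALSE)
  memb <- igraph::components(g2)$membership
  sizes <- sort(table(memb), decreasing = TRUE)
  renum <- stats::setNames(seq_along(sizes), names(sizes))
  ids <- rownames(A)
  cluster <- unname(renum[as.character(memb)])
  reps <- vapply(split(ids, cluster), function(members) {
    if (!is.null(seq_lengths)) {
      len <- seq_lengths[members]
      members <- members[order(-len, members)]
    } else {
      members <- sort(members)
    }
    members[1]
  }, character(1))
  out <- tibble(id = ids, cluster = cluster,
                representative = unname(reps[as.character(cluster)])) |>
    arrange(.data$cluster, .data$id)
  structure(out, iterations = iter, converged = converged,
            inflation = inflation,
            class = c("mcl_partition", class(out)))
}

#' Heuristic lysogeny flag from product annotations
#'
#' Flags a region as temperate when any annotated product matches a
#' lysogeny-marker keyword (integrases, serine recombinases, excisionases,
#' CI repressors, explicit lysogeny terms); otherwise
#' `"virulent-or-unknown"`. This is a keyword heuristic, not a lifestyle
#' predictor: absence of a marker is not evidence of virulence.
#'
#' @param products Character vector of product descriptions (may be empty).
#' @param keywords Marker keywords, matched case-insensitively.
#' @return `"temperate"` or `"virulent-or-unknown"`.
#' @export
#' @examples
#' lifestyle_flag(c("phage integrase"))
lifestyle_flag <- function(products,
                           keywords = c("integrase", "serine recombinase",
                                        "excisionase", "ci repressor",
                                        "lysogen")) {
  if (length(products) == 0L) return("virulent-or-unknown")
  hit <- vapply(tolower(products), function(p) {
    any(vapply(keywords, function(k) grepl(k, p, fixed = TRUE), logical(1)))
  }, logical(1))
  if (any(hit)) "temperate" else "virulent-or-unknown"
}
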