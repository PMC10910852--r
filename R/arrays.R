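# Repeat-anchored spacer extraction -----------------------------------------

#' Extract ordered spacers from a CRISPR array
#'
#' Anchors on occurrences of the conserved repeat and reads the inter-repeat
#' gaps as spacers, 5'->3'. Orientation is normalised so that the strand
#' matching the supplied repeat (not its reverse complement) reads left to
#' right: when the repeat is only found on the minus strand the subject is
#' reverse-complemented before extraction and the array is flagged
#' `strand = "-"`. Gaps whose length falls outside `spacer_len_bounds` (for
#' example the ~0.5-kb AT-rich insertion that splits some arrays) break the
#' array into segments; segments with at least one in-bounds spacer are kept
#' and tagged with a `segment` number.
#'
#' @param subject Sequence containing the array (amplicon or genome slice).
#' @param repeat_seq Repeat sequence (default [crispr1_repeat]).
#' @param max_mismatches Repeat-match tolerance in substitutions (default 3).
#' @param spacer_len_bounds Length-2 vector of allowed spacer lengths
#'   (default `c(20, 50)`; the canonical spacer is 32 nt).
#' @param isolate_id Identifier stored with each spacer.
#' @return A tibble of class `crispr_array` with columns `isolate_id`,
#'   `segment`, `spacer_index`, `spacer_id`, `sequence`, `start`, `end`,
#'   `strand`. Coordinates refer to the repeat-forward orientation of the
#'   subject. Attributes: `repeat_seq`, `source_interval`, `strand`.
#' @export
#' @examples
#' r <- crispr1_repeat
#' s1 <- strrep("ACGT", 8); s2 <- strrep("TGCA", 8)
#' arr <- extract_spacers(paste0(r, s1, r, s2, r), isolate_id = "iso1")
#' arr$sequence
extract_spacers <- function(subject, repeat_seq = crispr1_repeat,
                            max_mismatches = 3,
                            spacer_len_bounds = c(20, 50),
                            isolate_id = "isolate") {
  subject <- check_seq(subject, "subject")
  repeat_seq <- check_seq(repeat_seq, "repeat_seq")
  occ <- find_repeat_occurrences(subject, repeat_seq, max_mismatches)
  n_plus <- sum(occ$strand == "+")
  n_minus <- sum(occ$strand == "-")
  if (max(n_plus, n_minus) < 2L) {
    stop("no CRISPR array: fewer than 2 repeat occurrences on one strand",
         call. = FALSE)
  }
  strand <- "+"
  if (n_plus < 2L) {
    # array encoded on the minus strand: normalise
    subject <- revcomp(subject)
    occ <- find_repeat_occurrences(subject, repeat_seq, max_mismatches)
    strand <- "-"
  }
  occ <- occ[occ$strand == "+", , drop = FALSE]
  # greedy chain of non-overlapping repeat occurrences, left to right
  keep <- integer(0)
  last_end <- 0L
  for (i in seq_len(nrow(occ))) {
    if (occ$start[i] > last_end) {
      keep <- c(keep, i)
      last_end <- occ$end[i]
    }
  }
  occ <- occ[keep, , drop = FALSE]
  if (nrow(occ) < 2L) {
    stop("no CRISPR array: fewer than 2 repeat occurrences on one strand",
         call. = FALSE)
  }
  gap_start <- occ$end[-nrow(occ)] + 1L
  gap_end <- occ$start[-1L] - 1L
  gap_len <- gap_end - gap_start + 1L
  in_bounds <- gap_len >= spacer_len_bounds[1] & gap_len <= spacer_len_bounds[2]
  if (!any(in_bounds)) {
    stop("no CRISPR array: all inter-repeat gaps outside spacer length bounds",
         call. = FALSE)
  }
  # out-of-bounds gaps split the array into segments
  segment <- cumsum(c(1L, as.integer(!in_bounds[-length(in_bounds)])))
  idx <- which(in_bounds)
  out <- tibble(
    isolate_id = isolate_id,
    segment = match(segment[idx], unique(segment[idx])),
    spacer_index = seq_along(idx),
    spacer_id = sprintf("%s_sp%02d", isolate_id, seq_along(idx)),
    sequence = substring(subject, gap_start[idx], gap_end[idx]),
    start = gap_start[idx],
    end = gap_end[idx],
    strand = strand
  )
  structure(
    out,
    repeat_seq = repeat_seq,
    source_interval = c(occ$start[1], occ$end[nrow(occ)]),
    strand = strand,
    class = c("crispr_array", class(out))
  )
}

#' Extract arrays from a collection of sequences
#'
#' Applies [extract_spacers()] to every record; records without a detectable
#' array are dropped with a message.
#'
#' @param sequences Named character vector, data frame with id/sequence
#'   columns, or path to a FASTA file.
#' @inheritParams extract_spacers
#' @return One spacer tibble for the whole collection (`isolate_id`,
#'   `segment`, `spacer_index`, `spacer_id`, `sequence`, `start`, `end`,
#'   `strand`).
#' @export
extract_arrays <- function(sequences, repeat_seq = crispr1_repeat,
                           max_mismatches = 3, spacer_len_bounds = c(20, 50)) {
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences)) && file.exists(sequences)) {
    sequences <- read_fasta(sequences)
  }
  tbl <- as_seq_tbl(sequences, "isolate_id")
  res <- purrr::map(seq_len(nrow(tbl)), function(i) {
    tryCatch(
      extract_spacers(tbl$sequence[i], repeat_seq, max_mismatches,
                      spacer_len_bounds, isolate_id = tbl$isolate_id[i]),
      error = function(e) NULL
    )
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0L) {
    message(dropped, " record(s) without a detectable array were dropped")
  }
  out <- bind_rows(res)
  as_tibble(out)
}

#' Relative spacer positions along an array
#'
#' Maps spacer i of n to `(i - 1) / (n - 1)` along the 5'->3' array axis;
#' a single-spacer array maps to 0.5 by convention.
#'
#' @param array A `crispr_array` tibble (one isolate), or an integer spacer
#'   count.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
#' @examples
#' relative_positions(3)
relative_positions <- function(array) {
  n <- if (is.numeric(array)) as.integer(array) else nrow(array)
  if (is.na(n) || n < 1L) stop("array must contain at least one spacer",
                               call. = FALSE)
  if (n == 1L) return(0.5)
  (seq_len(n) - 1) / (n - 1)
}

#' Add relative positions to a multi-isolate spacer table
#'
#' @param spacers Spacer tibble with `isolate_id` and `spacer_index` columns.
#' @return The input with a `rel_pos` column appended.
#' @export
add_relative_positions <- function(spacers) {
  spacers |>
    group_by(.data$isolate_id) |>
    arrange(.data$spacer_index, .by_group = TRUE) |>
    mutate(rel_pos = relative_positions(dplyr::n())) |>
    ungroup()
}
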