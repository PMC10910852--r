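# Self-targeting spacer detection --------------------------------------------

#' Locate CRISPR array intervals on genome records
#'
#' Repeat occurrences extended by `window` bp on each side, with overlapping
#' or abutting extensions merged; spacer matches inside these intervals are
#' the array itself, not targets.
#'
#' @param sequences Named character vector or data frame with id/sequence
#'   columns.
#' @param repeat_seq Repeat sequence (default [crispr1_repeat]).
#' @param max_mismatches Repeat-match tolerance (default 3).
#' @param window Extension in bp (default 100).
#' @return Tibble: `record_id`, `start`, `end` (1-based inclusive, clipped
#'   to record bounds). Records without repeats contribute no rows.
#' @export
locate_array_intervals <- function(sequences, repeat_seq = crispr1_repeat,
                                   max_mismatches = 3, window = 100) {
  tbl <- as_seq_tbl(sequences, "record_id")
  out <- purrr::map(seq_len(nrow(tbl)), function(i) {
    occ <- find_repeat_occurrences(tbl$sequence[i], repeat_seq,
                                   max_mismatches)
    if (nrow(occ) == 0L) return(NULL)
    iv <- merge_intervals(pmax(1L, occ$start - as.integer(window)),
                          pmin(nchar(tbl$sequence[i]),
                               occ$end + as.integer(window)))
    iv$record_id <- tbl$record_id[i]
    iv
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(record_id = character(0), start = integer(0),
                  end = integer(0)))
  }
  select(out, "record_id", "start", "end")
}

#' Detect self-targeting events in a genome
#'
#' A self-targeting event is a spacer present both in a CRISPR array of the
#' chromosome and elsewhere in the same genome, outside any array interval.
#' Spacers are extracted from the chromosome's arrays, then searched against
#' every record; occurrences overlapping an array interval (repeat
#' occurrence +/- `window` bp) are discounted. A spacer whose only
#' extra-array occurrences lie on plasmid records is not an event - these
#' cases are set aside in a separate plasmid ledger.
#'
#' @param records Tibble with `record_id`, `role` (`"chromosome"` or
#'   `"plasmid"`), `sequence`; one genome.
#' @param repeat_seq Repeat sequence (default [crispr1_repeat]).
#' @param max_mismatches Stringency for "present elsewhere" (default 0,
#'   exact; set 4 to use the protospacer homology rule).
#' @param genome_id Identifier copied into the output.
#' @param repeat_max_mismatches Tolerance when locating repeats (default 3).
#' @param spacer_len_bounds Spacer length bounds for array extraction.
#' @param window Array-interval extension in bp (default 100).
#' @return List of class `self_target_scan`: `events` (one row per
#'   chromosomal target occurrence: `genome_id`, `spacer_id`, `spacer_seq`,
#'   `array_record`, `target_record`, `target_start`, `target_end`,
#'   `target_strand`, `mismatches`, `target_on_plasmid = FALSE`,
#'   `overlaps_prophage = NA`) and `plasmid_only` (same shape,
#'   `target_on_plasmid = TRUE`, for spacers matching only plasmids).
#' @export
detect_self_targeting <- function(records, repeat_seq = crispr1_repeat,
                                  max_mismatches = 0, genome_id = "genome",
                                  repeat_max_mismatches = 3,
                                  spacer_len_bounds = c(20, 50),
                                  window = 100) {
  stopifnot(is.data.frame(records),
            all(c("record_id", "role", "sequence") %in% names(records)))
  if (!any(records$role == "chromosome")) {
    stop("no chromosome record in `records`", call. = FALSE)
  }
  intervals <- locate_array_intervals(records, repeat_seq,
                                      repeat_max_mismatches, window)
  chrom <- records[records$role == "chromosome", , drop = FALSE]
  spacers <- purrr::map(seq_len(nrow(chrom)), function(i) {
    arr <- tryCatch(
      extract_spacers(chrom$sequence[i], repeat_seq, repeat_max_mismatches,
                      spacer_len_bounds, isolate_id = chrom$record_id[i]),
      error = function(e) NULL
    )
    if (is.null(arr)) return(NULL)
    as_tibble(arr)
  })
  spacers <- bind_rows(spacers)
  event_cols <- function() tibble(
    genome_id = character(0), spacer_id = character(0),
    spacer_seq = character(0), array_record = character(0),
    target_record = character(0), target_start = integer(0),
    target_end = integer(0), target_strand = character(0),
    mismatches = integer(0), target_on_plasmid = logical(0),
    overlaps_prophage = logical(0)
  )
  if (nrow(spacers) == 0L) {
    return(structure(list(events = event_cols(),
                          plasmid_only = event_cols()),
                     class = "self_target_scan"))
  }
  # one row per distinct spacer sequence; remember its source array record
  uniq <- spacers |>
    group_by(.data$sequence) |>
    summarise(spacer_id = .data$spacer_id[1],
              array_record = .data$isolate_id[1], .groups = "drop")
  role_of <- stats::setNames(records$role, records$record_id)
  occ <- purrr::map(seq_len(nrow(uniq)), function(i) {
    hits <- purrr::map(seq_len(nrow(records)), function(r) {
      if (nchar(uniq$sequence[i]) > nchar(records$sequence[r])) {
        return(empty_hits())
      }
      find_hits(uniq$sequence[i], records$sequence[r], max_mismatches,
                spacer_id = uniq$spacer_id[i],
                subject_id = records$record_id[r])
    })
    hits <- bind_rows(hits)
    if (nrow(hits) == 0L) return(NULL)
    # discount occurrences overlapping an array interval on their record
    in_array <- vapply(seq_len(nrow(hits)), function(j) {
      iv <- intervals[intervals$record_id == hits$subject_id[j], ,
                      drop = FALSE]
      nrow(iv) > 0L &&
        any(iv$start <= hits$end[j] & iv$end >= hits$start[j])
    }, logical(1))
    hits <- hits[!in_array, , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    tibble(
      genome_id = genome_id,
      spacer_id = uniq$spacer_id[i],
      spacer_seq = uniq$sequence[i],
      array_record = uniq$array_record[i],
      target_record = hits$subject_id,
      target_start = hits$start,
      target_end = hits$end,
      target_strand = hits$strand,
      mismatches = hits$mismatches,
      target_on_plasmid = unname(role_of[hits$subject_id]) == "plasmid",
      overlaps_prophage = NA
    )
  })
  occ <- bind_rows(occ)
  if (nrow(occ) == 0L) {
    return(structure(list(events = event_cols(),
                          plasmid_only = event_cols()),
                     class = "self_target_scan"))
  }
  chrom_spacers <- unique(occ$spacer_id[!occ$target_on_plasmid])
  events <- occ[!occ$target_on_plasmid, , drop = FALSE]
  plasmid_only <- occ[occ$target_on_plasmid &
                        !(occ$spacer_id %in% chrom_spacers), , drop = FALSE]
  structure(list(events = events, plasmid_only = plasmid_only),
            class = "self_target_scan")
}

#' @export
print.self_target_scan <- function(x, ...) {
  cat("<self_target_scan> ", nrow(x$events), " event(s), ",
      nrow(x$plasmid_only), " plasmid-only record(s)\n", sep = "")
  invisible(x)
}

#' Flag events overlapping called prophage regions
#'
#' @param events Event tibble (`$events` from [detect_self_targeting()]).
#' @param regions Prophage-region tibble from [call_regions()], with
#'   `subject_id` values matching the events' `target_record`; `NULL` or
#'   empty leaves `overlaps_prophage` unknown (`NA`).
#' @return `events` with `overlaps_prophage` set (`TRUE` iff the target
#'   interval intersects any region on its record).
#' @export
classify_events <- function(events, regions = NULL) {
  if (nrow(events) == 0L) return(events)
  if (is.null(regions) || nrow(regions) == 0L) {
    events$overlaps_prophage <- NA
    return(events)
  }
  events$overlaps_prophage <- vapply(seq_len(nrow(events)), function(i) {
    rg <- regions[regions$subject_id == events$target_record[i], ,
                  drop = FALSE]
    nrow(rg) > 0L && any(rg$start <= events$target_end[i] &
                           rg$end >= events$target_start[i])
  }, logical(1))
  events
}
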