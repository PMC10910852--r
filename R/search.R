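# Gapless k-mismatch search -------------------------------------------------
#
# The matcher reproduces the semantics of the protospacer filter: a hit is a
# full-length, gapless window of the subject whose Hamming distance to the
# spacer (or its reverse complement) is at most `max_mismatches`. Two exact
# strategies are used: a vectorised shifted-column scan (one comparison per
# pattern column, over all windows at once) and a pigeonhole-seeded search
# (split the pattern into max_mismatches + 1 exact segments; any window
# within distance k must contain one segment verbatim). Seeds are located
# with a zero-width PCRE lookahead so overlapping occurrences of periodic
# seeds are not lost.

# Hamming distance of every window of `subject` to `pattern` (plus strand).
window_mismatches <- function(pattern, subject) {
  m <- nchar(pattern)
  n <- nchar(subject)
  if (m == 0L) stop("empty pattern", call. = FALSE)
  if (m > n) return(integer(0))
  pat <- charToRaw(pattern)
  sub <- charToRaw(subject)
  nw <- n - m + 1L
  mm <- integer(nw)
  idx <- seq_len(nw)
  for (j in seq_len(m)) {
    mm <- mm + as.integer(sub[idx + (j - 1L)] != pat[j])
  }
  mm
}

# all start positions of `pattern` in `subject`, overlapping included
exact_occurrences <- function(pattern, subject) {
  r <- gregexpr(paste0("(?=\\Q", pattern, "\\E)"), subject, perl = TRUE)[[1]]
  if (r[1] == -1L) integer(0) else as.integer(r)
}

# one-strand k-mismatch scan; returns list(start, mismatches)
scan_one_strand <- function(pattern, subject, max_mismatches) {
  m <- nchar(pattern)
  n <- nchar(subject)
  if (m > n) return(list(start = integer(0), mismatches = integer(0)))
  nseg <- max_mismatches + 1L
  seg_len <- m %/% nseg
  if (max_mismatches == 0L) {
    st <- exact_occurrences(pattern, subject)
    return(list(start = st, mismatches = integer(length(st))))
  }
  if (seg_len < 4L) {
    # degenerate split: fall back to the full scan (still exact)
    mm <- window_mismatches(pattern, subject)
    keep <- which(mm <= max_mismatches)
    return(list(start = keep, mismatches = mm[keep]))
  }
  # pigeonhole seeding
  offsets <- c(0L, cumsum(c(rep(seg_len, nseg - 1L))))
  lens <- c(rep(seg_len, nseg - 1L), m - seg_len * (nseg - 1L))
  cand <- integer(0)
  for (i in seq_len(nseg)) {
    seg <- substr(pattern, offsets[i] + 1L, offsets[i] + lens[i])
    occ <- exact_occurrences(seg, subject)
    cand <- c(cand, occ - offsets[i])
  }
  cand <- sort(unique(cand))
  cand <- cand[cand >= 1L & cand <= n - m + 1L]
  if (length(cand) == 0L) {
    return(list(start = integer(0), mismatches = integer(0)))
  }
  pat <- charToRaw(pattern)
  mm <- vapply(cand, function(s) {
    sum(charToRaw(substr(subject, s, s + m - 1L)) != pat)
  }, integer(1))
  keep <- mm <= max_mismatches
  list(start = cand[keep], mismatches = mm[keep])
}

empty_hits <- function() {
  tibble(
    spacer_id = character(0), subject_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    mismatches = integer(0), masked = logical(0),
    mask_reason = character(0)
  )
}

#' Find gapless k-mismatch occurrences of a spacer
#'
#' Scans both strands of a subject sequence for full-length, gapless windows
#' within `max_mismatches` substitutions of the spacer. Coordinates are
#' 1-based inclusive on the forward strand of the subject; minus-strand hits
#' are windows matching the reverse complement of the spacer. Characters that
#' differ from the spacer letter (including ambiguity codes such as `N`)
#' count as mismatches.
#'
#' @param spacer Spacer sequence (single string over `ACGT`).
#' @param subject Subject sequence (single string).
#' @param max_mismatches Maximum Hamming distance (default 4, the full-length
#'   homology rule for 32-nt spacers).
#' @param spacer_id,subject_id Identifiers copied into the output.
#' @return A tibble with one row per hit: `spacer_id`, `subject_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `mismatches`, `masked` (all `FALSE`),
#'   `mask_reason`. Sorted by `start` then strand. A spacer longer than the
#'   subject yields zero rows with a warning.
#' @seealso [mask_array_proximal()], [scan_collection()]
#' @export
#' @examples
#' find_hits("ACGTACGT", "TTTACGTACGTTTT", max_mismatches = 0)
find_hits <- function(spacer, subject, max_mismatches = 4,
                      spacer_id = "spacer", subject_id = "subject") {
  spacer <- check_seq(spacer, "spacer")
  subject <- check_seq(subject, "subject")
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L) stop("`max_mismatches` must be >= 0", call. = FALSE)
  m <- nchar(spacer)
  if (m > nchar(subject)) {
    warning("spacer longer than subject; returning no hits", call. = FALSE)
    return(empty_hits())
  }
  fwd <- scan_one_strand(spacer, subject, max_mismatches)
  rev <- scan_one_strand(revcomp(spacer), subject, max_mismatches)
  out <- tibble(
    spacer_id = spacer_id,
    subject_id = subject_id,
    start = c(fwd$start, rev$start),
    end = c(fwd$start, rev$start) + m - 1L,
    strand = c(rep("+", length(fwd$start)), rep("-", length(rev$start))),
    mismatches = c(fwd$mismatches, rev$mismatches),
    masked = FALSE,
    mask_reason = NA_character_
  )
  arrange(out, .data$start, .data$strand)
}

#' Locate CRISPR repeat occurrences
#'
#' Finds every window of the subject within `max_mismatches` substitutions of
#' the repeat, on either strand. Used both to anchor spacer extraction and to
#' mask protospacer hits adjacent to CRISPR arrays.
#'
#' @param subject Subject sequence.
#' @param repeat_seq Repeat sequence (e.g. [crispr1_repeat]).
#' @param max_mismatches Substitution tolerance (default 3; terminal repeats
#'   are often degenerate).
#' @return Tibble with `start`, `end`, `strand`, `mismatches`, sorted by
#'   start. Overlapping occurrences are all reported.
#' @export
find_repeat_occurrences <- function(subject, repeat_seq,
                                    max_mismatches = 3) {
  subject <- check_seq(subject, "subject")
  repeat_seq <- check_seq(repeat_seq, "repeat_seq")
  if (nchar(repeat_seq) > nchar(subject)) {
    return(tibble(start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  m <- nchar(repeat_seq)
  fwd <- scan_one_strand(repeat_seq, subject, as.integer(max_mismatches))
  rev <- scan_one_strand(revcomp(repeat_seq), subject,
                         as.integer(max_mismatches))
  out <- tibble(
    start = c(fwd$start, rev$start),
    end = c(fwd$start, rev$start) + m - 1L,
    strand = c(rep("+", length(fwd$start)), rep("-", length(rev$start))),
    mismatches = c(fwd$mismatches, rev$mismatches)
  )
  arrange(out, .data$start, .data$strand)
}

#' Mask protospacer hits adjacent to CRISPR repeats
#'
#' Spacer matches inside or near a CRISPR array are the array itself, not a
#' target. A hit is masked when the gap between its interval and any repeat
#' occurrence interval is at most `window` bp (overlap counts as gap 0).
#' Masked hits are retained with `masked = TRUE` and reason
#' `"repeat-proximal"` so downstream counts can exclude them without losing
#' the record.
#'
#' @param hits Hit tibble from [find_hits()] (single subject).
#' @param repeat_occurrences Tibble with `start` and `end` columns, as from
#'   [find_repeat_occurrences()] on the same subject.
#' @param window Maximum gap in bp (default 100).
#' @return `hits` with `masked`/`mask_reason` updated.
#' @export
mask_array_proximal <- function(hits, repeat_occurrences, window = 100) {
  if (window < 0) stop("`window` must be non-negative", call. = FALSE)
  if (nrow(hits) == 0L || is.null(repeat_occurrences) ||
      nrow(repeat_occurrences) == 0L) {
    return(hits)
  }
  masked <- vapply(seq_len(nrow(hits)), function(i) {
    any(interval_gap(hits$start[i], hits$end[i],
                     repeat_occurrences$start,
                     repeat_occurrences$end) <= window)
  }, logical(1))
  hits$masked <- hits$masked | masked
  hits$mask_reason <- ifelse(masked, "repeat-proximal", hits$mask_reason)
  hits
}

#' Scan a sequence collection for protospacers
#'
#' Runs [find_hits()] for every spacer against every subject, masking hits
#' within `mask_window` bp of a repeat occurrence when `repeat_seq` is given.
#' Subjects are processed one at a time (repeat occurrences computed once per
#' subject), so memory use is independent of collection size.
#'
#' @param spacers Named character vector of spacer sequences, or a data frame
#'   with id and sequence (or `representative`) columns, e.g. the output of
#'   [cluster_summary()].
#' @param subjects Named character vector of subject sequences, a data frame
#'   with id/sequence columns, or a path to a FASTA file.
#' @param max_mismatches Substitution tolerance per hit (default 4).
#' @param repeat_seq Optional repeat used for masking (default `NULL`, no
#'   masking).
#' @param mask_window Masking distance in bp (default 100).
#' @param repeat_max_mismatches Tolerance when locating repeats (default 3).
#' @return One hit tibble for the whole collection; masked hits retained
#'   with `masked = TRUE`.
#' @export
scan_collection <- function(spacers, subjects, max_mismatches = 4,
                            repeat_seq = NULL, mask_window = 100,
                            repeat_max_mismatches = 3) {
  sp <- as_seq_tbl(spacers, "spacer_id")
  if (is.character(subjects) && length(subjects) == 1L &&
      is.null(names(subjects)) && file.exists(subjects)) {
    subjects <- read_fasta(subjects)
  }
  su <- as_seq_tbl(subjects, "subject_id")
  if (nrow(sp) == 0L || nrow(su) == 0L) return(empty_hits())
  res <- purrr::map(seq_len(nrow(su)), function(i) {
    subject <- su$sequence[i]
    occ <- NULL
    if (!is.null(repeat_seq)) {
      occ <- find_repeat_occurrences(subject, repeat_seq,
                                     repeat_max_mismatches)
    }
    hits <- purrr::map(seq_len(nrow(sp)), function(j) {
      if (nchar(sp$sequence[j]) > nchar(subject)) return(empty_hits())
      find_hits(sp$sequence[j], subject, max_mismatches,
                spacer_id = sp$spacer_id[j], subject_id = su$subject_id[i])
    })
    hits <- bind_rows(hits)
    if (!is.null(occ) && nrow(hits) > 0L) {
      hits <- mask_array_proximal(hits, occ, mask_window)
    }
    hits
  })
  bind_rows(res)
}
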