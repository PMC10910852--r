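dna_alphabet <- c("A", "C", "G", "T")

#' Reverse complement
#'
#' Vectorised reverse complement of DNA strings. Case is preserved; characters
#' outside `ACGTacgt` (e.g. `N`) are reversed but left unchanged.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACCGT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

# lexicographically smaller of a sequence and its reverse complement;
# identifies a spacer with its opposite-strand reading
canonical_seq <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

check_seq <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`", arg, "` must be a single string", call. = FALSE)
  }
  if (nchar(x) == 0L) stop("`", arg, "` must be non-empty", call. = FALSE)
  toupper(x)
}

# run code under a temporary RNG state when seed is supplied
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# coerce (named character vector | tibble with id/sequence columns) to a
# two-column tibble; used by every collection-facing entry point
as_seq_tbl <- function(x, id_col = "id") {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    out <- tibble(id = ids, sequence = toupper(unname(x)))
  } else if (is.data.frame(x)) {
    seq_col <- intersect(c("sequence", "representative"), names(x))[1]
    known_id <- intersect(c(id_col, "spacer_id", "subject_id", "record_id",
                            "cluster_id", "id"), names(x))[1]
    if (is.na(seq_col) || is.na(known_id)) {
      stop("data frame input needs an id column and a sequence column",
           call. = FALSE)
    }
    out <- tibble(id = as.character(x[[known_id]]),
                  sequence = toupper(x[[seq_col]]))
  } else {
    stop("expected a named character vector or a data frame", call. = FALSE)
  }
  names(out)[1] <- id_col
  out
}

# merge sorted/unsorted 1-based closed intervals; abutting intervals merge
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

# uniform integer draw on [lo, hi]; safe when lo == hi (no sample() scalar
# expansion)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  as.integer(sample(seq.int(lo, hi), 1))
}

# gap in bp between two closed intervals; 0 when they overlap or abut
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}
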