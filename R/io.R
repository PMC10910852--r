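# FASTA / TSV / BED / JSON input-output --------------------------------------

#' Read a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1)
  out
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector or data frame with id/sequence
#'   columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  tbl <- as_seq_tbl(sequences, "id")
  x <- Biostrings::DNAStringSet(tbl$sequence)
  names(x) <- tbl$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a coordinate table as 1-based TSV
#'
#' Prepends a comment line declaring the coordinate convention.
#'
#' @param x Data frame with 1-based inclusive `start`/`end` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_1based <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive intervals to BED
#'
#' @param x Data frame with a record/subject id column and 1-based
#'   `start`/`end` columns.
#' @param id_col Name of the id column (default the first column).
#' @return Tibble with BED columns `chrom`, `chromStart` (0-based),
#'   `chromEnd` (exclusive), `name`.
#' @export
intervals_to_bed <- function(x, id_col = names(x)[1]) {
  tibble(
    chrom = as.character(x[[id_col]]),
    chromStart = as.integer(x$start) - 1L,
    chromEnd = as.integer(x$end),
    name = if ("spacer_id" %in% names(x)) x$spacer_id else
      paste0("region", seq_len(nrow(x)))
  )
}

#' Serialize synthetic ground truth to JSON
#'
#' @param truth Truth list from [simulate_cohort()] or
#'   [simulate_subjects()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
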