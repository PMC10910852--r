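# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's search machinery: every window is enumerated and
# compared character by character.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

chars <- function(s) strsplit(s, "")[[1]]

# naive one-strand Hamming scan: every window, character comparison
naive_scan <- function(pattern, subject, max_mm) {
  p <- chars(pattern)
  s <- chars(subject)
  m <- length(p)
  n <- length(s)
  if (m > n) return(data.frame(start = integer(0), mismatches = integer(0)))
  res <- lapply(seq_len(n - m + 1L), function(i) {
    mm <- sum(s[i:(i + m - 1L)] != p)
    if (mm <= max_mm) data.frame(start = i, mismatches = mm) else NULL
  })
  do.call(rbind, c(res, list(data.frame(start = integer(0),
                                        mismatches = integer(0)))))
}

# both-strand oracle matching the find_hits contract
naive_hits <- function(spacer, subject, max_mm) {
  fwd <- naive_scan(spacer, subject, max_mm)
  rev <- naive_scan(revcomp(spacer), subject, max_mm)
  out <- rbind(
    if (nrow(fwd)) cbind(fwd, strand = "+") else NULL,
    if (nrow(rev)) cbind(rev, strand = "-") else NULL
  )
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(start = integer(0), mismatches = integer(0),
                      strand = character(0)))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# brute-force two-sample KS statistic by ECDF enumeration
naive_ks_d <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(vapply(xs, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, numeric(1)))
}

# mutate exactly k positions of a sequence
mutate_k <- function(seq, k) {
  cs <- chars(seq)
  pos <- sample(length(cs), k)
  for (p in pos) cs[p] <- sample(setdiff(c("A", "C", "G", "T"), cs[p]), 1)
  paste(cs, collapse = "")
}
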