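Package: spacernet
Title: CRISPR Spacer Catalogues, Sharing Networks, and Prophage Target Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing CRISPR1 arrays from Escherichia coli isolate
    collections: repeat-anchored spacer extraction, spacer deduplication and
    known/new classification, isolate spacer-sharing networks with a
    permutation-null edge threshold and module detection, gapless k-mismatch
    protospacer search with CRISPR-locus masking, median-absolute-deviation
    based prophage-region calling, Markov clustering of near-identical viral
    sequences, and self-targeting event detection. Includes a synthetic-data
    generator with machine-readable ground truth so the whole pipeline can be
    exercised end-to-end without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
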