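---
title: "Methods: CRISPR spacer networks and prophage target mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR spacer networks and prophage target mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacernet)
```

## The analysis

`spacernet` implements a complete analysis chain for CRISPR1 arrays in
*Escherichia coli* isolate collections. Type I-E CRISPR1 arrays consist of a
conserved 29-nt direct repeat (`crispr1_repeat`,
`5'-CGGTTTATCCCCGCTGGCGCGGGGAACAC-3'`) alternating with ~32-nt spacers
acquired from foreign DNA. The chain is:

1. **Extraction** — spacers are read as the inter-repeat gaps of
   repeat-anchored arrays (`extract_spacers()`).
2. **Cataloguing** — spacers are deduplicated into clusters and classified
   known/new against a reference set (`cluster_spacers()`,
   `classify_known_new()`).
3. **Network** — isolates sharing spacer clusters are linked, edge
   significance is calibrated on a permutation null, and modules are
   extracted (`permutation_null()`, `build_network()`, `detect_modules()`).
4. **Protospacer search** — spacers are matched against subject genomes
   under a gapless, full-length, at-most-4-mismatch rule, and matches near
   CRISPR repeats are masked (`find_hits()`, `mask_array_proximal()`).
5. **Prophage calling** — subjects whose targets cluster positionally
   (low MAD) and reach 10 hits get a candidate prophage region;
   near-identical viral sequences are deduplicated at 95 % identity / 85 %
   coverage and grouped by Markov clustering (`call_regions()`,
   `dedup_graph()`, `mcl_cluster()`).
6. **Self-targeting** — spacers present both in an array and elsewhere on
   the same chromosome are flagged, with a plasmid exception
   (`detect_self_targeting()`).

Every stage consumes and produces tibbles, so a study is a pipe of data
frames; `run_pipeline()` composes the stages under one `spacer_config()`.

## The matching model

A protospacer hit is a full-length window of the subject, on either strand,
whose Hamming distance to the spacer is at most `max_mismatches` (default
4, the conventional cut-off for 32-nt spacers). Gaps are never allowed, so
Hamming distance — not edit distance — is the right metric, and the search
is exact rather than heuristic. The implementation splits the spacer into
`max_mismatches + 1` contiguous segments; by pigeonhole, any window within
the tolerance contains at least one segment verbatim, so exact segment
occurrences (found with a zero-width regular-expression lookahead, which
also returns overlapping occurrences of periodic seeds) delimit a candidate
set that is then verified by direct byte comparison. When the split would
produce segments shorter than 4 nt the code falls back to a vectorised
full scan over all windows, which is exact by construction. Ambiguity
codes in subjects (`N` etc.) never match a spacer letter and therefore
count as mismatches — conservative on low-quality contigs.

Hits within 100 bp of a repeat occurrence (gap between the two closed
intervals, overlap counting as 0) are the array itself, not targets; they
are retained with `masked = TRUE` so nothing is silently dropped, and all
downstream counts use unmasked hits only.

## Array extraction and orientation

Extraction anchors on repeat occurrences at up to 3 substitutions
(terminal repeats are often degenerate; the tolerance is configurable).
Orientation is normalised so that the strand matching the supplied repeat —
not its reverse complement — reads 5'→3'; reverse-complementing the input
therefore changes only the reported strand flag. Inter-repeat gaps outside
the 20–50-nt spacer bounds (such as the ~0.5-kb AT-rich insertion known to
split some arrays) break the array into tagged segments rather than
aborting extraction. Relative spacer positions use `(i − 1)/(n − 1)` along
the 5'→3' axis, with the single-spacer convention 0.5 — the midpoint is
the least informative choice when no polarity can be read from one spacer.

## Network calibration

Two isolates are linked when they share at least one spacer cluster; the
link weight is one of three indices (binary Jaccard over cluster sets,
weighted Jaccard `Σmin/Σmax` over count vectors, Tanimoto
`a·b/(‖a‖²+‖b‖²−a·b)`). The binary Jaccard is the default; on cohorts of
this kind the three differ only marginally. Edge significance is
calibrated on a permutation null: each of 500 replicates redistributes the
pooled spacer multiset across isolates while preserving every isolate's
spacer count exactly (a random permutation partitioned by the original
counts), pair similarities with at least one shared spacer are pooled
across pairs and replicates, and the edge threshold is the 95th
nearest-rank percentile of that pool. Nearest-rank is used because it is
reproducible without interpolation ambiguity; pooling across pairs (rather
than per-pair thresholds) matches the use of a single global cut-off.
Edges *at* the threshold are kept: only connections strictly below it are
removed. Module detection is pluggable (greedy modularity by default,
deterministic; label propagation and connected components as
alternatives); map-equation optimisers are deliberately out of scope, so
any external community detector can be swapped in at the partition level.

## Prophage calling

For every subject with at least two unmasked hits the unscaled median
absolute deviation of hit start positions is recorded
(`stats::mad(constant = 1)`; no 1.4826 consistency factor because MAD is
used as a dispersion proxy, not a normal-scale estimator). Genomes whose
targets fall in a prophage show many hits with low MAD; genomes with
scattered targets show high MAD (about a quarter of the genome length for
uniform positions). Subjects reaching 10 unmasked hits get one candidate
region: minimum hit start to maximum hit end, widened by 25-kb flanks and
clipped to the sequence bounds. One region per subject is a documented
limitation — two well-separated prophages produce a single merged span.

Candidate regions and phage sequences are deduplicated at the species
level: 95 % identity over 85 % coverage, coverage measured against the
*shorter* sequence (the containment-friendly reading; a prophage extracted
with flanks still matches its phage). Identity is computed by anchoring
shared 13-mers, grouping them by diagonal, scoring each diagonal's gapless
span by direct comparison, and greedily chaining non-overlapping segments;
both orientations are tried. This gapless anchor chain is a deliberate
simplification — the dedup decision needs identity estimates only near the
95 % regime, where substitution divergence dominates; a full
dynamic-programming aligner serves as the oracle in tests for sequences up
to a few kb.

Markov clustering is implemented from scratch: self-loops of weight 1,
column-stochastic normalisation, then alternating expansion (matrix
squaring) and inflation (elementwise power 2.0 with column
renormalisation), pruning entries below `1e-6`, until the maximum
elementwise change drops below the same tolerance or 100 iterations.
Clusters are the connected components of the limit matrix's support, so
disconnected components can never merge. Representatives are the longest
member, ties broken lexicographically. The lifestyle flag over annotation
products (integrase, serine recombinase, excisionase, CI repressor,
lysogeny keywords) is labelled a heuristic: it detects lysogeny markers,
and their absence is *not* evidence of a virulent phage.

## Self-targeting

A self-targeting event is a spacer present in a chromosomal CRISPR array
and at one or more loci outside every array interval (repeat occurrences
± 100 bp, merged) of the same genome. Matching is exact by default — the
appropriate stringency for asking whether the *same* spacer recurs — with
the 4-mismatch protospacer rule available as an option. A spacer whose
only extra-array occurrences sit on plasmid records is not an event; those
cases are set aside in a separate plasmid ledger so they remain auditable.
Spacers belonging to any array count as array-resident in multi-array
genomes.

## The synthetic-data generator

The generator exists so that every stage can be tested against
machine-readable truth without external databases. `simulate_cohort()`
emulates an isolate collection with latent module structure: each module
owns a simulated 40-kb phage; its pool of 40 spacers is cut from that
phage at jittered-grid positions (protospacers spread along a phage genome
rather than i.i.d., which also keeps the span of planted targets
well-behaved), on random strands, with 0–4 substitutions planted per
spacer at frequencies (0.6, 0.2, 0.1, 0.05, 0.05). Isolates draw 6–16
spacers from their module pool — matching the reported average of ~11
spacers per array while staying inside the observed 2–32 range; the lower
floor keeps pairwise overlap informative at desk scale — plus ~10 %
private decoys with no planted origin (spacers whose targets fall outside
the simulated universe). `simulate_subjects()` implants one prophage per
genome and plants a controlled number of protospacers inside it (or
scatters them genome-wide as the negative control);
`simulate_selftarget_genome()` constructs a chromosome + plasmid pair
exercising the array-only / array+prophage / array+plasmid truth table.

What the generator does **not** emulate: real phage gene content,
sequencing error, assembly artefacts, GC skew, repeat degeneracy beyond
planted substitutions, horizontal spacer transfer between modules, and
array-internal duplications. Passing tests therefore demonstrate that the
algorithms implement their contracts exactly on data whose generative
process is known — not that biological arrays meet these idealisations.

## Problem sizes and numerical choices

The test suite runs the full chain at desk scale: oracle equivalence on
1000 random spacer/subject pairs (subjects up to 10 kb) against an
independent reference matcher; prophage recovery on 100 genomes of 120 kb
with one 40-kb prophage and 10–15 planted targets each (100/100 regions
contain the truth); null conservation on all 500 replicates of a
50-isolate cohort; module recovery (adjusted Rand ≥ 0.9) across 10 seeds;
MCL component integrity on 100 random graphs. These sizes were chosen as
the smallest at which each property is non-trivial. All randomness flows
through explicit seeds; a pipeline's master seed derives per-stage child
seeds at fixed offsets so stages are individually reproducible.

Degenerate inputs are handled by contract: empty spacer lists error in the
generator but yield empty tables in scans; a spacer longer than its
subject warns and returns no hits; single-position MADs are 0; a
percentile threshold on an all-zero null is 0; cluster/module ids are
renumbered by decreasing size with lexicographic tie-breaks.

## Known limitations

* One merged prophage region per subject (by design, above).
* The anchor-chain identity underestimates identity for highly rearranged
  pairs; it is calibrated for near-identical sequences, which is the only
  regime the 95 %/85 % rule consults.
* The permutation null conditions on per-isolate spacer counts only; it
  does not preserve within-isolate spacer adjacency.
* The lifestyle flag is a keyword heuristic and reports
  `virulent-or-unknown`, never `virulent`.
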