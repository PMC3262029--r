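---
title: "Tandem motif scanning in TSS-relative promoter windows: models and methods"
author: "ltsmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem motif scanning in TSS-relative promoter windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltsmscan)
```

## The motif model

A *tandem motif* is an ordered series of short fixed DNA flanks
separated by spacers whose lengths are constrained but whose bases are
not. The motivating case is the localized tandem sequence motif (LTSM)
of ribosomal protein (RP) gene promoters: two `ATC` flanks separated by
a 7-bp spacer, strictly oriented with transcription, typically starting
about 62 bp downstream of the transcription start site (TSS). Because
`ATC` is 3 bp, the two `T` bases of a canonical instance sit exactly
10 bp apart — roughly one turn of the double helix — which is the
structural argument for treating the spacer length, and not the spacer
content, as the constrained feature. The spacer base distribution is
modelled as the local genomic background.

`tandem_motif()` generalizes this to any number of flanks and to spacer
*ranges*: the tripartite variant `ATC`-8-`ATC`-6-`ATC` is simply a
3-flank motif, and the ±1-bp spacer variants are single-gap motifs with
spacers 6 or 8. A scan enumerates every (start, spacer assignment,
strand) combination, so a tripartite region remains discoverable by the
bipartite variant scans — that property is load-bearing, because the
tripartite pattern was historically found through exactly such variant
scans.

Scanning conventions, each chosen once and applied everywhere:

* **Mismatches** (`max_mismatch`) are counted over flank positions
  only; spacer bases are wildcards. The degenerate search "one flank
  base may deviate" is `max_mismatch = 1`.
* **`N` carries no evidence**: a hard-masked base on a flank position
  disqualifies a match outright, even when the mismatch budget is not
  exhausted. An `N` on a spacer position is irrelevant.
* **Soft masking** is a switch, mirroring scans with and without
  repeat masking: `ignore_mask` compares lowercase case-insensitively,
  `skip_masked` suppresses any match whose span touches a lowercase or
  `N` base.
* **Reverse-strand hits** are reported at the leftmost sense-strand
  base they cover, so histograms use a single coordinate system
  regardless of orientation.
* Overlapping and nested matches are all reported; only exact
  (start, length, strand) duplicates are merged, keeping the
  lexicographically smallest spacer assignment. Two identical spans
  reached through different spacer assignments are therefore one hit —
  a convention, since flanks with self-overlapping structure can in
  principle realize the same span twice.

## Coordinates

TSS-relative positions use a no-zero axis: +1 is the TSS base itself,
−1 the base immediately upstream. A −500..+500 window is exactly
1000 bp with the TSS base at 0-based scan index 500, which is the only
convention under which a 1000-bp window can carry its TSS "at position
500". `rel_to_index()`/`index_to_rel()` are the bijection; minus-strand
promoters are reverse-complemented at extraction so index 0 is always
the most upstream base. Windows that overrun a contig edge are dropped
by default (with a logged reason) rather than N-padded, because
padding would silently deflate per-position expectations in histogram
bins near the edge; `clip_policy = "pad"` is available when a uniform
window count matters more.

The genome-wide scan window +21..+100 requires, by default, the whole
match inside the window (`containment = "full"`); the preferred-window
classification +52..+82 tests the hit *start* against inclusive
bounds. The anchor point of a hit is nowhere defined by the source
analyses, so start-anchoring is this package's documented convention,
consistent with a canonical start near +62 inside +52..+82.

## Positional statistics

Histograms bin hit starts with 20-bp bins anchored at +1 downstream
and −1 upstream, so the named bin [+21,+40] exists exactly and no bin
straddles the TSS. Under an i.i.d. (or first-order Markov) background
the probability that a given start position carries an exact match is
the product of background probabilities over flank bases — for the
canonical motif under uniform composition, $(1/4)^6 \approx 2.44
\times 10^{-4}$ — and the expected hit count in an $L$-bp window is
$(L - 13 + 1) \cdot p$ per strand, e.g. $988 \times 4^{-6} = 0.2412$
for 1 kb. Reverse-strand expectations are computed on the
reverse-complement motif, so compositionally skewed backgrounds give
asymmetric strand expectations, as they should (`ATC` vs `GAT`
content).

Per-bin enrichment compares observed counts to $n_\mathrm{seq} \cdot p
\cdot (\text{feasible starts in bin})$, where feasibility excludes
starts too close to the window end to host a full match. Upper-tail
p-values are Poisson — expected counts are small and the number of
scanned positions large, which is the Poisson limit of the exact
binomial; the binomial tail is available behind `tail = "binomial"`.
Across bins the p-values are Benjamini–Hochberg adjusted, with 0.05 as
the conventional significance line. Because the Poisson tail on
discrete counts is conservative (super-uniform under the null), the
calibration check in the test suite verifies both the total hit count
against its analytic expectation and the approximate uniformity of
null p-values.

`fisher_exact_2x2()` implements the two-sided exact test by the
point-probability rule — summing hypergeometric probabilities of all
tables with the observed margins whose probability does not exceed the
observed table's — in log space, with a relative tie tolerance of
1e-7 because tie handling is where implementations legitimately
differ. It is verified against full enumeration (all tables with
margins up to 25) and against `stats::fisher.test()`. The historical
large-vs-small ribosomal subunit comparison (26 of 47 large-subunit
genes positive, 35 of 81 overall) gives p ≈ 0.013 from the natural
table [[26,21],[9,25]]; no 2×2 table constructible from those printed
counts yields the once-reported 0.143, so this package implements the
standard test and does not attempt to reproduce that value.

## TSS catalog handling

CAGE-style tag clusters are reduced to a representative TSS, the
5′-most tag: minimum coordinate on `+`, maximum on `-`, ties broken by
highest tag count then lowest coordinate. Catalog deduplication treats
"overlapping" records as identical (chrom, coordinate, strand) triples
and keeps the first in deterministic sort order — reproducibility in
place of an arbitrary choice. Concordance against a reference TSS set
scores each gene by the minimum absolute distance over its candidate
TSSs (unsigned by default; the signed offset of the closest candidate
is available), with genes lacking candidates reported as uncovered and
excluded from the mean.

## The synthetic promoter generator

`synthetic_promoters()` emulates the one thing the pipeline needs to
be tested end to end: promoter windows of known base composition with
motif instances planted at controlled TSS-relative positions, strands
and spacer lengths. Planting *overwrites* the window rather than
inserting, so coordinates stay valid; spacer bases of planted
instances are refilled from the background so planted sets do not
distort composition estimates; minus-strand instances are written as
the reverse complement, with the recorded position being the leftmost
sense base — exactly the `start` a scan reports. One root seed spawns
a deterministic sub-stream per promoter, so any subset of a simulated
set is reproducible on its own and two runs are byte-identical.

What the generator does *not* emulate: real promoters have CpG
islands, core promoter elements, repeat families with internal
structure, and position-dependent composition, none of which an
i.i.d./first-order background reproduces. Passing tests on synthetic
data therefore demonstrate correctness of the scanning, coordinate and
statistical machinery under a known truth — not that any biological
promoter set is enriched.

`rp_like_promoter_panel()` is a special fixed benchmark: 81 synthetic
promoter windows carrying canonical instances in the published
composition of the RP promoter set — 35 sense-strand instances
starting in +52..+82, 2 sense-strand instances elsewhere, 13
reverse-complement instances, and tripartite instances at the typical
location in four promoters named after the genes known to carry them
(RPS15A, RPL17, RPL3, RPS24). Its background is drawn from {A, G}
only and planted spacers are filled with `A`: neither `ATC` nor `GAT`
can occur by chance (each needs a base the background lacks), and the
planted instances were checked not to create secondary pairings at any
scanned spacer, so a scan recovers exactly the planted composition.
This panel is synthetic stand-in data — it validates that
scan/classify/collapse reproduce a known partition (50/35/2/13 hits
and 4 tripartite-positive genes), it is not the published hit table.

## Problem sizes and numerical choices

The validation suite runs at the scale the analyses call for: 500
random kilobase sequences (uniform and GC = 0.6) against a brute-force
enumeration oracle at 0 and 1 mismatches; 20,000 unplanted 1-kb
promoters for background calibration (total forward-strand hits within
4 binomial SDs of $20{,}000 \times 0.2412$, null p-values uniform by a
Kolmogorov–Smirnov check); 200 planted promoters for recovery
(200/200 at the exact position and strand, histogram mode [+61,+80]);
all 2×2 tables with margins ≤ 25 for the Fisher oracle (agreement to
1e-10); 1000 random vectors for the BH step-up reference (1e-12); 100
random contigs for the extraction and BED round-trip oracles. The
whole suite completes in well under five minutes on one CPU.

Degenerate inputs are contracts, not accidents: a sequence shorter
than the minimal motif length yields an empty hit table (not an
error); an empty hit set yields zero-count histograms and zero
classification totals; a zero-margin contingency table returns p = 1
with a warning; masked-base exclusion can leave a background estimate
dominated by its pseudo-counts (1 per symbol/transition), which is the
intended shrinkage.

## Command-line use

`inst/scripts/ltsm-tools.R` wraps the exported functions as `simulate`,
`scan` (presets `ltsm`, `ltsm-genomewide`, `tripartite`), `classify`
and `histogram` subcommands. Outputs are TSV with a `#`-prefixed
provenance block carrying the package version and an md5 hash of the
canonical configuration string; identical configurations reproduce
outputs byte for byte.

## Known limitations

* Flanks are literal `A,C,G,T` strings: no IUPAC degeneracy and no
  position-weight-matrix scoring (mismatch counting is the only
  relaxation).
* Background models stop at first order; spacer composition is never
  scored.
* Gene-level positivity is a pure any-transcript collapse; no
  alternative-promoter inference is attempted.
* TSS catalog ingestion expects simple TSV/annotation formats, not the
  native distribution formats of specific databases.

```{r example, eval = FALSE}
# A minimal end-to-end run on synthetic data:
sim <- synthetic_promoters(200, plant_fraction = 1,
                           plant_position = 62, seed = 1)
hits <- scan_promoters(sim$promoters, ltsm_motif())
classify_hits(hits)$totals
histogram_argmax(build_histogram(hits, c(-500, 500), 20, 200))
```
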