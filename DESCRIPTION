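Package: ltsmscan
Title: Tandem Sequence Motif Scanning and Positional Enrichment in
    Promoter Regions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and positional analysis of localized tandem
    sequence motifs (LTSMs) in transcription start site (TSS)-relative
    promoter windows.  Provides a strand-aware scanner for multi-flank
    tandem DNA motifs with variable spacer lengths and optional flank
    mismatches, promoter window extraction from genome FASTA plus
    GTF/GFF3/BED annotation with soft/hard masking preserved,
    TSS-relative positional histograms and orientation classification,
    analytic background models with per-bin enrichment statistics
    (Poisson tails, Benjamini-Hochberg correction, exact Fisher tests,
    hypergeometric set overlap), TSS catalog reduction and concordance
    scoring, and a synthetic promoter simulator with planted ground
    truth so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
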