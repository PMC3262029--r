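# Positional analysis: histograms of TSS-relative hit starts, the
# preferred-window/orientation classification and transcript->gene
# collapse. Bins are anchored at +1 downstream and -1 upstream so the
# bin [+21,+40] exists exactly; no bin straddles the TSS.

#' Bin hit starts into a TSS-relative histogram
#'
#' Bins the start coordinate (leftmost covered base, no-zero
#' TSS-relative axis) of every hit, separately per strand.  Downstream
#' bins are `[+1,+20]`, `[+21,+40]`, ...; upstream bins `[-20,-1]`,
#' `[-40,-21]`, ...; edge bins are truncated at the window bounds.
#'
#' @param hits Hit table carrying `rel_start` and `strand` (see
#'   [scan_promoters()]).
#' @param window Inclusive window `c(upstream_rel, downstream_rel)`.
#' @param bin_width Bin width in bp.
#' @param n_sequences Number of promoters scanned (kept as metadata for
#'   enrichment computations).
#' @return A `PositionalHistogram`: data frame with `bin_lo`, `bin_hi`,
#'   `count_fwd`, `count_rev` plus attributes `bin_width`, `window`,
#'   `n_sequences`.
#' @export
build_histogram <- function(hits, window = c(-500L, 500L), bin_width = 20L,
                            n_sequences = NA_integer_) {
  u <- as.integer(window[1]); d <- as.integer(window[2])
  bin_width <- as.integer(bin_width)
  if (u == 0L || d == 0L || u > d || bin_width < 1L)
    stop("invalid window or bin width")
  bins <- histogram_bins(u, d, bin_width)
  r <- as.integer(hits$rel_start)
  if (length(r) && (any(r == 0L) || any(r < u | r > d)))
    stop("hit start(s) outside the histogram window")
  bi <- bin_index_of(r, u, d, bin_width)
  bins$count_fwd <- tabulate(bi[hits$strand == "+"], nbins = nrow(bins))
  bins$count_rev <- tabulate(bi[hits$strand == "-"], nbins = nrow(bins))
  structure(bins, bin_width = bin_width, window = c(u, d),
            n_sequences = n_sequences,
            class = c("PositionalHistogram", "data.frame"))
}

histogram_bins <- function(u, d, w) {
  lo <- integer(0); hi <- integer(0)
  if (u < 0L) {
    h <- seq.int(-1L, u, by = -w)
    lo <- c(lo, rev(pmax(h - w + 1L, u)))
    hi <- c(hi, rev(h))
  }
  dlo <- seq.int(max(1L, u), d, by = w)
  lo <- c(lo, dlo)
  hi <- c(hi, pmin(dlo + w - 1L, d))
  data.frame(bin_lo = lo, bin_hi = hi)
}

# 1-based bin index on the bin table from histogram_bins()
bin_index_of <- function(r, u, d, w) {
  n_up <- if (u < 0L) as.integer(ceiling(-u / w)) else 0L
  as.integer(ifelse(r > 0L,
                    n_up + (r - max(1L, u)) %/% w + 1L,
                    n_up - (-r - 1L) %/% w))
}

#' Bin with the highest forward (or reverse) count
#'
#' @param histogram A [build_histogram()] result.
#' @param strand `"forward"` or `"reverse"`.
#' @return One-row data frame (`bin_lo`, `bin_hi`, count); ties resolve
#'   to the most upstream bin.
#' @export
histogram_argmax <- function(histogram, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  cnt <- if (strand == "forward") histogram$count_fwd
         else histogram$count_rev
  i <- which.max(cnt)
  data.frame(bin_lo = histogram$bin_lo[i], bin_hi = histogram$bin_hi[i],
             count = cnt[i])
}

#' Classify hits by position and orientation
#'
#' Partitions hits into `preferred_forward` (sense-strand hits starting
#' inside the preferred window, bounds inclusive), `elsewhere_forward`
#' (other sense-strand hits) and `reverse` (all antisense hits) — the
#' three-way split used to summarize canonical-motif occurrences in
#' promoter sets.
#'
#' @param hits Hit table with `rel_start` and `strand`.
#' @param preferred_window Inclusive TSS-relative interval, default
#'   `c(52, 82)`.
#' @return List with `hits` (input plus a `category` factor) and
#'   `totals` (named vector: `total`, `preferred_forward`,
#'   `elsewhere_forward`, `reverse`).
#' @export
classify_hits <- function(hits, preferred_window = c(52L, 82L)) {
  lo <- as.integer(preferred_window[1]); hi <- as.integer(preferred_window[2])
  if (lo == 0L || hi == 0L || lo > hi)
    stop("invalid preferred window")
  cat_ <- ifelse(hits$strand == "-", "reverse",
                 ifelse(hits$rel_start >= lo & hits$rel_start <= hi,
                        "preferred_forward", "elsewhere_forward"))
  cat_ <- factor(cat_, levels = c("preferred_forward",
                                  "elsewhere_forward", "reverse"))
  hits$category <- cat_
  totals <- c(total = nrow(hits),
              preferred_forward = sum(cat_ == "preferred_forward"),
              elsewhere_forward = sum(cat_ == "elsewhere_forward"),
              reverse = sum(cat_ == "reverse"))
  list(hits = hits, totals = totals,
       preferred_window = c(lo, hi))
}

#' Collapse transcript-level hits to gene-level positivity
#'
#' A gene is positive when at least one of its transcripts carries at
#' least one hit.  Alternative transcripts sharing a motif instance
#' therefore count once at the gene level.
#'
#' @param hits Hit table (needs `sequence_id`; `gene_id` is taken from
#'   `tx2gene` if supplied, else from the hits).
#' @param tx2gene Optional named character vector mapping transcript id
#'   to gene id.
#' @return List with `n_positive_transcripts`, `n_positive_genes`, and
#'   `per_gene` (named list of positive transcript ids per gene).
#' @export
collapse_to_genes <- function(hits, tx2gene = NULL) {
  if (!nrow(hits))
    return(list(n_positive_transcripts = 0L, n_positive_genes = 0L,
                per_gene = list()))
  tx <- as.character(hits$sequence_id)
  if (is.null(tx2gene)) {
    if (is.null(hits$gene_id))
      stop("need gene_id column or tx2gene map")
    gene <- as.character(hits$gene_id)
  } else {
    gene <- unname(tx2gene[tx])
    if (anyNA(gene))
      stop("transcript(s) without gene mapping: ",
           paste(unique(tx[is.na(gene)])[1:3], collapse = ", "))
  }
  per_gene <- lapply(split(tx, gene), unique)
  list(n_positive_transcripts = length(unique(tx)),
       n_positive_genes = length(per_gene),
       per_gene = per_gene)
}
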