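# Independent oracles used across the suite. These deliberately avoid
# the package's scan engine internals: the brute-force scanner walks
# every (start, spacer, strand) candidate and compares characters
# extracted with substring(); the extraction oracle walks the genome
# one base at a time in transcription direction.

random_dna <- function(n, freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
        collapse = "")
}

# all spacer assignments as a list of integer vectors, lexicographic
oracle_spacer_assignments <- function(ranges) {
  grids <- lapply(ranges, function(r) seq.int(r[1], r[2]))
  out <- list(integer(0))
  for (g in grids)
    out <- unlist(lapply(out, function(pre)
      lapply(g, function(v) c(pre, v))), recursive = FALSE)
  out
}

# mismatch count per start for one flank at a fixed offset, all starts
# at once via substring()
oracle_flank_mm <- function(seq_u, starts, offset, flank) {
  fc <- strsplit(flank, "", fixed = TRUE)[[1]]
  mm <- integer(length(starts))
  for (k in seq_along(fc)) {
    ch <- substring(seq_u, starts + offset + k - 1L,
                    starts + offset + k - 1L)
    mm <- mm + (ch != fc[k]) + (ch == "N") * 1000L
  }
  mm
}

oracle_scan_strand <- function(seq, motif, max_mm, skip_masked) {
  n <- nchar(seq)
  seq_u <- toupper(seq)
  rows <- list()
  for (sp in oracle_spacer_assignments(motif$spacer_ranges)) {
    offs <- cumsum(c(0L, head(nchar(motif$flanks), -1L) + sp))
    L <- offs[length(offs)] + nchar(motif$flanks[length(motif$flanks)])
    if (n < L) next
    starts <- seq_len(n - L + 1L)  # 1-based
    mm <- integer(length(starts))
    for (j in seq_along(motif$flanks))
      mm <- mm + oracle_flank_mm(seq_u, starts, offs[j], motif$flanks[j])
    ok <- mm <= max_mm
    if (skip_masked) {
      masked_ok <- vapply(starts, function(s)
        !grepl("[a-zN]", substr(seq, s, s + L - 1L)), logical(1))
      ok <- ok & masked_ok
    }
    if (any(ok))
      rows[[length(rows) + 1L]] <-
        data.frame(start = starts[ok] - 1L, length = L,
                   spacers = paste(sp, collapse = ","),
                   mismatches = mm[ok], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

oracle_scan <- function(seq, motif, max_mm = 0L,
                        strands = "both", mask_policy = "ignore_mask") {
  skip <- mask_policy == "skip_masked"
  n <- nchar(seq)
  pieces <- list()
  if (strands %in% c("both", "forward")) {
    h <- oracle_scan_strand(seq, motif, max_mm, skip)
    if (!is.null(h)) { h$strand <- "+"; pieces <- c(pieces, list(h)) }
  }
  if (strands %in% c("both", "reverse")) {
    h <- oracle_scan_strand(reverse_complement(seq), motif, max_mm, skip)
    if (!is.null(h)) {
      h$start <- n - h$start - h$length
      h$strand <- "-"
      pieces <- c(pieces, list(h))
    }
  }
  if (!length(pieces))
    return(data.frame(start = integer(), length = integer(),
                      spacers = character(), mismatches = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  out <- out[order(out$start, out$strand, out$length), , drop = FALSE]
  out <- out[!duplicated(out[c("start", "length", "strand")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_hits_equal_oracle <- function(hits, oracle) {
  expect_equal(hits$start, oracle$start)
  expect_equal(hits$length, oracle$length)
  expect_equal(hits$strand, oracle$strand)
  expect_equal(hits$mismatches, oracle$mismatches)
  expect_equal(hits$spacers, oracle$spacers)
}

# literal BH step-up reference
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  if (m > 1L) for (i in (m - 1L):1L) q[i] <- min(q[i], q[i + 1L])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# full-enumeration two-sided Fisher p via rational choose() arithmetic
fisher_reference <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; N <- r1 + r2
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  p0 <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# Poisson upper tail from the partial sum of the pmf
poisson_tail_reference <- function(obs, lambda) {
  if (obs <= 0) return(1)
  1 - exp(-lambda) * sum(lambda^(0:(obs - 1)) / factorial(0:(obs - 1)))
}

# per-base walking extraction oracle: follows the transcript 5'->3'
walk_extract <- function(contig, tss, strand, u, d) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", a = "t", c = "g",
            g = "c", t = "a", N = "N", n = "n")
  rels <- seq.int(u, d)
  rels <- rels[rels != 0L]
  out <- character(length(rels))
  for (i in seq_along(rels)) {
    r <- rels[i]
    if (strand == "+") {
      g <- tss + if (r > 0L) r - 1L else r
      out[i] <- substr(contig, g, g)
    } else {
      g <- tss - (if (r > 0L) r - 1L else r)
      out[i] <- comp[[substr(contig, g, g)]]
    }
  }
  paste(out, collapse = "")
}
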