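# Analytic background expectations and enrichment statistics. Flank
# positions carry all the information: a match probability is the
# product of background probabilities over flank bases, spacer bases
# contribute a factor of 1. Reverse-strand probabilities are computed
# on the reverse-complement motif so compositional strand skew is
# respected.

#' Background base-composition models
#'
#' `estimate_background()` fits a maximum-likelihood i.i.d. (order 0)
#' or first-order Markov (order 1) model with a pseudo-count of 1 per
#' symbol/transition; `N` bases are always excluded, lowercase bases
#' are excluded under `mask_policy = "skip_masked"`.
#' `uniform_background()` and `gc_background(gc)` are analytic
#' shortcuts.
#'
#' @param sequences Character vector of DNA strings.
#' @param order 0 (i.i.d.) or 1 (first-order Markov; rows of the
#'   transition matrix sum to 1 and the start distribution is the
#'   stationary distribution of the fitted chain).
#' @param mask_policy See [scan_config()].
#' @param gc Total G+C fraction.
#' @return A `BackgroundModel` list with elements `order`, `freqs`, and
#'   for order 1 also `trans` and `start`.
#' @examples
#' estimate_background(c("AAAA", "TTTT"))
#' gc_background(0.6)
#' @export
estimate_background <- function(sequences, order = 0L,
                                mask_policy = c("ignore_mask",
                                                "skip_masked")) {
  mask_policy <- match.arg(mask_policy)
  order <- as.integer(order)
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  if (!length(sequences)) stop("need at least one sequence")
  bases <- c("A", "C", "G", "T")
  counts <- setNames(numeric(4), bases)
  tcounts <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (s in sequences) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    keep <- if (mask_policy == "skip_masked") ch %in% bases
            else toupper(ch) %in% bases
    chu <- toupper(ch)
    tb <- table(factor(chu[keep], levels = bases))
    counts <- counts + as.numeric(tb)
    if (order == 1L && length(ch) > 1L) {
      ok <- keep[-length(keep)] & keep[-1L]
      if (any(ok)) {
        from <- factor(chu[-length(chu)][ok], levels = bases)
        to <- factor(chu[-1L][ok], levels = bases)
        tcounts <- tcounts + table(from, to)
      }
    }
  }
  freqs <- (counts + 1) / (sum(counts) + 4)
  if (order == 0L)
    return(structure(list(order = 0L, freqs = freqs),
                     class = "BackgroundModel"))
  trans <- (tcounts + 1) / rowSums(tcounts + 1)
  ev <- eigen(t(trans))
  i <- which.min(abs(ev$values - 1))
  start <- Re(ev$vectors[, i]); start <- start / sum(start)
  names(start) <- bases
  structure(list(order = 1L, freqs = freqs, trans = trans, start = start),
            class = "BackgroundModel")
}

#' @rdname estimate_background
#' @export
uniform_background <- function()
  structure(list(order = 0L,
                 freqs = c(A = .25, C = .25, G = .25, T = .25)),
            class = "BackgroundModel")

#' @rdname estimate_background
#' @export
gc_background <- function(gc) {
  stopifnot(gc >= 0, gc <= 1)
  structure(list(order = 0L,
                 freqs = c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                           T = (1 - gc) / 2)),
            class = "BackgroundModel")
}

#' Probability of an exact motif match at one position
#'
#' Probability that the background emits all flank bases of the motif
#' (realized with the given spacers) at a fixed start position on one
#' strand.  Spacer positions are free.  Order-1 models use exact path
#' summation: transition products within flanks and `(P^(s+1))` between
#' the last base of one flank and the first base of the next across an
#' s-bp gap.
#'
#' @param motif A [tandem_motif()].
#' @param spacers Realized spacer lengths.
#' @param background A `BackgroundModel`.
#' @return Probability in \[0, 1\].
#' @examples
#' motif_probability(ltsm_motif(), 7, uniform_background())  # (1/4)^6
#' @export
motif_probability <- function(motif, spacers, background) {
  flank_offsets(motif, spacers)  # validates spacers
  fl <- strsplit(motif$flanks, "", fixed = TRUE)
  if (background$order == 0L)
    return(prod(background$freqs[unlist(fl)]))
  P <- background$trans
  p <- background$start[fl[[1]][1]]
  for (j in seq_along(fl)) {
    b <- fl[[j]]
    if (length(b) > 1L)
      for (k in 2:length(b)) p <- p * P[b[k - 1L], b[k]]
    if (j < length(fl)) {
      Pg <- matpow(P, as.integer(spacers[j]) + 1L)
      p <- p * Pg[b[length(b)], fl[[j + 1L]][1L]]
    }
  }
  unname(p)
}

matpow <- function(P, k) {
  out <- diag(nrow(P)); dimnames(out) <- dimnames(P)
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2L
  }
  out
}

#' Expected number of motif matches in a window
#'
#' Sums `(window_len - realized_length + 1) * motif_probability` over
#' all spacer assignments and the strands allowed by `config`.
#' Reverse-strand probabilities come from the reverse-complement motif,
#' so skewed backgrounds give asymmetric strand expectations.
#'
#' @param window_len Scanned sequence length in bp.
#' @param motif A [tandem_motif()].
#' @param config A [scan_config()] (only `strands` is used).
#' @param background A `BackgroundModel`.
#' @return Expected match count.
#' @examples
#' expected_hits(1000, ltsm_motif(), scan_config("forward"),
#'               uniform_background())  # 988 * 4^-6
#' @export
expected_hits <- function(window_len, motif, config = scan_config(),
                          background = uniform_background()) {
  window_len <- as.integer(window_len)
  grid <- spacer_grid(motif)
  rcm <- rc_motif(motif)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    sp <- grid[r, ]
    L <- sum(nchar(motif$flanks)) + sum(sp)
    npos <- max(0L, window_len - L + 1L)
    if (!npos) next
    if (config$strands %in% c("both", "forward"))
      total <- total + npos * motif_probability(motif, sp, background)
    if (config$strands %in% c("both", "reverse"))
      total <- total + npos * motif_probability(rcm, rev(sp), background)
  }
  total
}

#' Per-bin positional enrichment against the analytic background
#'
#' For each histogram bin, the expected number of hit starts is the
#' number of scanned promoters times the per-position match
#' probability, summed over the bin's feasible start positions (those
#' where a full match still fits inside the window) and over spacer
#' assignments and strands.  Upper-tail p-values are Poisson
#' (`P(X >= observed)`; exact binomial available via
#' `tail = "binomial"`), corrected across bins with Benjamini-Hochberg.
#'
#' @param histogram A [build_histogram()] result with `n_sequences` set.
#' @param motif A [tandem_motif()].
#' @param background A `BackgroundModel`.
#' @param strands Strand(s) the observed counts cover.
#' @param tail `"poisson"` (default) or `"binomial"`.
#' @return Data frame: `bin_lo`, `bin_hi`, `observed_fwd`,
#'   `observed_rev`, `expected`, `p`, `q`.
#' @export
bin_enrichment <- function(histogram, motif,
                           background = uniform_background(),
                           strands = c("both", "forward", "reverse"),
                           tail = c("poisson", "binomial")) {
  strands <- match.arg(strands)
  tail <- match.arg(tail)
  win <- attr(histogram, "window")
  n_seq <- attr(histogram, "n_sequences")
  if (is.na(n_seq)) stop("histogram must carry n_sequences")
  u <- win[1]; d <- win[2]
  Lwin <- (if (u < 0L) -u else 1L - u) + d
  tssi <- if (u < 0L) -u else 1L - u
  grid <- spacer_grid(motif)
  rcm <- rc_motif(motif)
  expected <- numeric(nrow(histogram))
  trials <- numeric(nrow(histogram))
  blo <- rel_to_index(histogram$bin_lo, tssi)
  n_strands <- if (strands == "both") 2L else 1L
  for (r in seq_len(nrow(grid))) {
    sp <- grid[r, ]
    L <- sum(nchar(motif$flanks)) + sum(sp)
    p_pos <- 0
    if (strands %in% c("both", "forward"))
      p_pos <- p_pos + motif_probability(motif, sp, background)
    if (strands %in% c("both", "reverse"))
      p_pos <- p_pos + motif_probability(rcm, rev(sp), background)
    hi_idx_feasible <- Lwin - L  # last feasible 0-based start
    if (hi_idx_feasible < 0L) next
    bhi <- pmin(rel_to_index(histogram$bin_hi, tssi), hi_idx_feasible)
    nfeas <- pmax(0L, bhi - blo + 1L)
    expected <- expected + n_seq * p_pos * nfeas
    trials <- trials + n_seq * nfeas * n_strands
  }
  observed <- switch(strands,
                     both = histogram$count_fwd + histogram$count_rev,
                     forward = histogram$count_fwd,
                     reverse = histogram$count_rev)
  p <- if (tail == "poisson") {
    ppois(observed - 1L, expected, lower.tail = FALSE)
  } else {
    pr <- ifelse(trials > 0, expected / trials, 0)
    stats::pbinom(observed - 1L, round(trials), pr, lower.tail = FALSE)
  }
  data.frame(bin_lo = histogram$bin_lo, bin_hi = histogram$bin_hi,
             observed_fwd = histogram$count_fwd,
             observed_rev = histogram$count_rev,
             expected = expected, p = p, q = bh_adjust(p))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with
#' relative tolerance 1e-7 for ties).  Computed in log space.
#'
#' @param table 2x2 matrix (or length-4 vector `a,b,c,d` filled by row)
#'   of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))  # 1/3
#' @export
fisher_exact_2x2 <- function(table) {
  x <- as.integer(round(as.numeric(table)))
  if (length(x) != 4L || anyNA(x) || any(x < 0L))
    stop("need a 2x2 table of non-negative counts")
  if (is.matrix(table)) {
    a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  } else {
    a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  }
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0L) {
    warning("zero margin: p = 1")
    return(1)
  }
  xs <- max(0L, c1 - r2):min(r1, c1)
  lp <- dhyper(xs, c1, c2, r1, log = TRUE)
  lp0 <- dhyper(a, c1, c2, r1, log = TRUE)
  min(1, sum(exp(lp[lp <= lp0 + log1p(1e-7)])))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up false discovery rate adjustment (order-preserving
#' with the input); a validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set overlap test
#'
#' Overlap size and upper-tail hypergeometric p-value
#' `P(X >= |A intersect B|)` for two gene sets drawn from a universe of
#' known size.
#'
#' @param setA,setB Character vectors of identifiers.
#' @param universe_size Size of the sampling universe (>= |A union B|).
#' @return List with `overlap`, `n_a`, `n_b`, `universe_size`,
#'   `expected`, `p`.
#' @export
set_overlap_test <- function(setA, setB, universe_size) {
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  universe_size <- as.integer(universe_size)
  if (universe_size < length(union(setA, setB)))
    stop("universe smaller than |A union B|")
  k <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB)
  p <- phyper(k - 1L, nA, universe_size - nA, nB, lower.tail = FALSE)
  list(overlap = k, n_a = nA, n_b = nB, universe_size = universe_size,
       expected = nA * nB / universe_size, p = p)
}
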