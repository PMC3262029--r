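#' Define a tandem DNA motif
#'
#' A tandem motif is an ordered series of short fixed flank strings
#' separated by spacers of constrained but possibly variable length.
#' The canonical localized tandem sequence motif (LTSM) found in
#' ribosomal protein gene promoters is two `ATC` flanks separated by a
#' 7-bp spacer; its tripartite relative is `ATC`-8-`ATC`-6-`ATC`.
#' Spacer bases are unconstrained: only flank positions are compared
#' during scanning.
#'
#' @param flanks Character vector of at least two DNA strings over
#'   `A`,`C`,`G`,`T` (uppercased on input).
#' @param spacer_ranges List with one `c(min, max)` integer pair per gap
#'   between consecutive flanks.
#' @param name Short label used in reports.
#' @return An object of class `TandemMotif`.
#' @examples
#' tandem_motif(c("ATC", "ATC"), list(c(7, 7)))
#' @export
tandem_motif <- function(flanks, spacer_ranges, name = "tandem") {
  flanks <- toupper(as.character(flanks))
  if (length(flanks) < 2L)
    stop("a tandem motif needs at least 2 flanks")
  if (any(nchar(flanks) == 0L) || any(grepl("[^ACGT]", flanks)))
    stop("flanks must be non-empty strings over A,C,G,T")
  if (!is.list(spacer_ranges) || length(spacer_ranges) != length(flanks) - 1L)
    stop("need exactly one spacer range per gap (", length(flanks) - 1L, ")")
  spacer_ranges <- lapply(spacer_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || anyNA(r) || r[1] < 0L || r[1] > r[2])
      stop("each spacer range must satisfy 0 <= min <= max")
    r
  })
  structure(
    list(name = as.character(name), flanks = flanks,
         spacer_ranges = spacer_ranges),
    class = "TandemMotif")
}

#' @export
print.TandemMotif <- function(x, ...) {
  gaps <- vapply(x$spacer_ranges, function(r)
    if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2]),
    character(1))
  parts <- character(2L * length(x$flanks) - 1L)
  parts[seq_along(x$flanks) * 2L - 1L] <- x$flanks
  parts[seq_along(gaps) * 2L] <- gaps
  cat("TandemMotif <", x$name, ">: ", paste(parts, collapse = "-"),
      " (length ", motif_min_length(x),
      if (motif_max_length(x) != motif_min_length(x))
        paste0("-", motif_max_length(x)), " bp)\n", sep = "")
  invisible(x)
}

#' Canonical and tripartite LTSM motif presets
#'
#' `ltsm_motif()` is the canonical ATC-7-ATC tandem (13 bp);
#' `ltsm_tripartite_motif()` is ATC-8-ATC-6-ATC (23 bp), and
#' `ltsm_variant_motif(spacer)` gives the single-gap ATC tandem with any
#' fixed or ranged spacer (e.g. 6 or 8 bp spacer variants).
#'
#' @param spacer Integer spacer length, or `c(min, max)` range.
#' @return A [tandem_motif()] object.
#' @examples
#' ltsm_motif()
#' ltsm_tripartite_motif()
#' @export
ltsm_motif <- function() tandem_motif(c("ATC", "ATC"), list(c(7, 7)), "LTSM")

#' @rdname ltsm_motif
#' @export
ltsm_tripartite_motif <- function()
  tandem_motif(c("ATC", "ATC", "ATC"), list(c(8, 8), c(6, 6)),
               "LTSM-tripartite")

#' @rdname ltsm_motif
#' @export
ltsm_variant_motif <- function(spacer)
  tandem_motif(c("ATC", "ATC"), list(spacer),
               paste0("LTSM-spacer", paste(unique(range(spacer)),
                                           collapse = "_")))

#' Motif length bounds and flank offsets
#'
#' `motif_min_length()`/`motif_max_length()` give the total match length
#' under the shortest/longest spacer assignment.  `flank_offsets()`
#' returns the 0-based offset of each flank's first base within a match
#' realized with the given spacer lengths; the canonical LTSM has flank
#' offsets 0 and 10, which places the two `T` bases exactly 10 bp (one
#' helical turn) apart.
#'
#' @param motif A [tandem_motif()].
#' @param spacers Integer vector of realized spacer lengths.
#' @return Integer vector (offsets) or single integer (lengths).
#' @examples
#' flank_offsets(ltsm_motif(), 7)
#' motif_min_length(ltsm_tripartite_motif())
#' @export
flank_offsets <- function(motif, spacers) {
  spacers <- as.integer(spacers)
  if (length(spacers) != length(motif$spacer_ranges))
    stop("need one realized spacer per gap")
  for (j in seq_along(spacers)) {
    r <- motif$spacer_ranges[[j]]
    if (spacers[j] < r[1] || spacers[j] > r[2])
      stop("spacer ", j, " (", spacers[j], ") outside allowed range [",
           r[1], ",", r[2], "]")
  }
  cumsum(c(0L, nchar(motif$flanks)[-length(motif$flanks)] + spacers))
}

#' @rdname flank_offsets
#' @export
motif_min_length <- function(motif)
  sum(nchar(motif$flanks)) +
    sum(vapply(motif$spacer_ranges, `[`, integer(1), 1L))

#' @rdname flank_offsets
#' @export
motif_max_length <- function(motif)
  sum(nchar(motif$flanks)) +
    sum(vapply(motif$spacer_ranges, `[`, integer(1), 2L))

# all realized spacer assignments, rows in lexicographic order
spacer_grid <- function(motif) {
  vals <- lapply(motif$spacer_ranges, function(r) seq.int(r[1], r[2]))
  g <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)
  g <- as.matrix(g)[, rev(seq_along(vals)), drop = FALSE]
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' Reverse complement with mask preservation
#'
#' Reverse-complements DNA keeping soft masking intact: lowercase stays
#' lowercase, `N`/`n` map to themselves.  Vectorized over the input.
#'
#' @param seq Character vector of DNA strings over `A,C,G,T,N` in either
#'   case.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATC")
#' reverse_complement("aTgN")
#' @export
reverse_complement <- function(seq) {
  seq <- as.character(seq)
  bad <- regexpr("[^ACGTNacgtn]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("non-nucleotide character '", substr(seq[i], bad[i], bad[i]),
         "' at position ", bad[i],
         if (length(seq) > 1L) paste0(" of element ", i))
  }
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", seq)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Reverse-complement a tandem motif
#'
#' The motif whose forward-strand matches are exactly the
#' reverse-strand matches of `motif`: flank order reversed, each flank
#' reverse-complemented, spacer ranges reversed.
#'
#' @param motif A [tandem_motif()].
#' @return A [tandem_motif()].
#' @export
rc_motif <- function(motif) {
  tandem_motif(rev(reverse_complement(motif$flanks)),
               rev(motif$spacer_ranges),
               paste0(motif$name, "-rc"))
}

#' Scanning configuration
#'
#' @param strands Which strands to scan: `"both"`, `"forward"` (sense),
#'   or `"reverse"` (matches on the reverse complement).
#' @param max_mismatch Maximum number of mismatching flank bases
#'   (spacer bases are never compared).  Must be smaller than the total
#'   number of flank bases.
#' @param mask_policy `"ignore_mask"` compares soft-masked (lowercase)
#'   bases case-insensitively; `"skip_masked"` suppresses any match
#'   whose span touches a lowercase or `N` base.  Hard-masked `N` bases
#'   never match a flank base under either policy.
#' @param position_window Optional inclusive TSS-relative interval
#'   (no-zero coordinates, e.g. `c(21, 100)`) that matches must lie in;
#'   requires a known TSS index at scan time.
#' @param containment With a `position_window`, `"full"` requires the
#'   whole match inside the window, `"start_only"` only its start.
#' @return An object of class `ScanConfig`.
#' @export
scan_config <- function(strands = c("both", "forward", "reverse"),
                        max_mismatch = 0L,
                        mask_policy = c("ignore_mask", "skip_masked"),
                        position_window = NULL,
                        containment = c("full", "start_only")) {
  strands <- match.arg(strands)
  mask_policy <- match.arg(mask_policy)
  containment <- match.arg(containment)
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L)
    stop("max_mismatch must be a non-negative integer")
  if (!is.null(position_window)) {
    position_window <- as.integer(position_window)
    if (length(position_window) != 2L || anyNA(position_window) ||
        any(position_window == 0L) ||
        position_window[1] > position_window[2])
      stop("position_window must be two nonzero coordinates with low <= high")
  }
  structure(list(strands = strands, max_mismatch = max_mismatch,
                 mask_policy = mask_policy,
                 position_window = position_window,
                 containment = containment),
            class = "ScanConfig")
}
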