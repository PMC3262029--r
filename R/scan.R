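# Scanner engine. Sequences are handled as character vectors internally;
# mismatch counts per flank placement are computed by vectorized shifted
# comparisons, an N on a flank position is weighted so heavily (+1000)
# that it can never fit any realistic mismatch budget.

.N_PENALTY <- 1000L

empty_hits <- function() {
  data.frame(sequence_id = character(), start = integer(),
             length = integer(), strand = character(),
             spacers = character(), mismatches = integer(),
             matched_text = character(), stringsAsFactors = FALSE)
}

# hits for one reading strand; chars_orig is the sequence as read on
# that strand (case preserved); returns 0-based starts on that strand
.scan_one_strand <- function(chars_orig, motif, max_mm, skip_masked) {
  n <- length(chars_orig)
  if (n < motif_min_length(motif)) return(NULL)
  chars_u <- toupper(chars_orig)
  flank_chars <- strsplit(motif$flanks, "", fixed = TRUE)
  flank_len <- lengths(flank_chars)
  mmv <- vector("list", length(flank_chars))
  for (j in seq_along(flank_chars)) {
    lf <- flank_len[j]
    if (n < lf) return(NULL)
    m <- integer(n - lf + 1L)
    for (k in seq_len(lf)) {
      ck <- chars_u[k:(n - lf + k)]
      m <- m + (ck != flank_chars[[j]][k]) + (ck == "N") * .N_PENALTY
    }
    mmv[[j]] <- m
  }
  if (skip_masked) {
    bad <- (chars_orig != chars_u) | (chars_u == "N")
    cbad <- cumsum(bad)
  }
  grid <- spacer_grid(motif)
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    sp <- grid[r, ]
    offs <- cumsum(c(0L, flank_len[-length(flank_len)] + sp))
    L <- offs[length(offs)] + flank_len[length(flank_len)]
    if (n < L) next
    m <- n - L + 1L
    tot <- mmv[[1L]][seq_len(m)]
    for (j in seq_along(offs)[-1L])
      tot <- tot + mmv[[j]][seq_len(m) + offs[j]]
    ok <- tot <= max_mm
    if (skip_masked) {
      spanbad <- cbad[seq_len(m) + L - 1L] - c(0L, cbad)[seq_len(m)]
      ok <- ok & (spanbad == 0L)
    }
    idx <- which(ok)
    if (length(idx))
      out[[r]] <- data.frame(start = idx - 1L, length = L,
                             spacers = paste(sp, collapse = ","),
                             mismatches = tot[idx],
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Test a motif at a single position
#'
#' Low-level primitive: does the motif, realized with the given spacer
#' lengths, match the forward strand of `seq` at 0-based position
#' `pos`?  Mismatches are counted over flank positions only; spacer
#' bases are wildcards.
#'
#' @param seq DNA string (soft masking as lowercase, hard masking as N).
#' @param pos 0-based start position of the candidate match.
#' @param motif A [tandem_motif()].
#' @param spacers Realized spacer lengths, one per gap.
#' @param max_mismatch Allowed flank-base mismatches.
#' @param mask_policy See [scan_config()].
#' @return A one-row hit data frame, or `NULL` if there is no match.
#' @examples
#' match_at("ATCAAAAAAAATC", 0, ltsm_motif(), 7)
#' @export
match_at <- function(seq, pos, motif, spacers,
                     max_mismatch = 0L,
                     mask_policy = c("ignore_mask", "skip_masked")) {
  mask_policy <- match.arg(mask_policy)
  offs <- flank_offsets(motif, spacers)
  L <- offs[length(offs)] + nchar(motif$flanks[length(motif$flanks)])
  n <- nchar(seq)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 0L || pos + L > n)
    stop("pos ", pos, " out of range for a ", L, "-bp match in a ", n,
         "-bp sequence")
  span <- substr(seq, pos + 1L, pos + L)
  if (mask_policy == "skip_masked" && grepl("[a-zN]", span)) return(NULL)
  span_u <- toupper(span)
  mm <- 0L
  for (j in seq_along(motif$flanks)) {
    got <- substr(span_u, offs[j] + 1L, offs[j] + nchar(motif$flanks[j]))
    gc <- strsplit(got, "", fixed = TRUE)[[1]]
    fc <- strsplit(motif$flanks[j], "", fixed = TRUE)[[1]]
    mm <- mm + sum(gc != fc) + sum(gc == "N") * .N_PENALTY
  }
  if (mm > max_mismatch) return(NULL)
  data.frame(sequence_id = "seq", start = pos, length = L, strand = "+",
             spacers = paste(as.integer(spacers), collapse = ","),
             mismatches = mm, matched_text = span,
             stringsAsFactors = FALSE)
}

#' Scan a sequence for tandem motif matches
#'
#' Enumerates every combination of start position, spacer assignment
#' and strand allowed by `config`.  Hits are reported in ascending
#' start order with `+` before `-` at equal starts; exact duplicates
#' (same start, length and strand, e.g. from alternative spacer
#' assignments realizing the same span) are merged keeping the
#' lexicographically smallest spacer assignment.  Overlapping and
#' nested distinct matches are all kept.  For `-` hits, `start` is the
#' leftmost covered base on the sense sequence and `matched_text` the
#' sense-strand substring; flank/spacer structure is read on the
#' reverse complement.
#'
#' @param seq DNA string (lowercase = soft-masked, `N` = hard-masked).
#' @param motif A [tandem_motif()].
#' @param config A [scan_config()].
#' @param sequence_id Identifier recorded in the hit table.
#' @param tss_scan_index Optional 0-based index of the TSS base, needed
#'   only when `config$position_window` is set.
#' @return Hit data frame with columns `sequence_id`, `start` (0-based),
#'   `length`, `strand`, `spacers`, `mismatches`, `matched_text`.
#' @examples
#' scan_sequence("GGATCGGGGGGGATCGG", ltsm_motif())
#' @export
scan_sequence <- function(seq, motif, config = scan_config(),
                          sequence_id = "seq", tss_scan_index = NULL) {
  seq <- as.character(seq)
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop("seq must be a single non-empty DNA string")
  if (grepl("[^ACGTNacgtn]", seq)) {
    bad <- regexpr("[^ACGTNacgtn]", seq)
    stop("non-nucleotide character '", substr(seq, bad, bad),
         "' at position ", bad)
  }
  if (config$max_mismatch >= sum(nchar(motif$flanks)))
    stop("max_mismatch must be smaller than the total number of flank bases")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  skip <- config$mask_policy == "skip_masked"
  pieces <- list()
  if (config$strands %in% c("both", "forward")) {
    h <- .scan_one_strand(chars, motif, config$max_mismatch, skip)
    if (!is.null(h)) { h$strand <- "+"; pieces <- c(pieces, list(h)) }
  }
  if (config$strands %in% c("both", "reverse")) {
    rc_chars <- rev(chartr("ACGTacgtNn", "TGCAtgcaNn", chars))
    h <- .scan_one_strand(rc_chars, motif, config$max_mismatch, skip)
    if (!is.null(h)) {
      h$start <- n - h$start - h$length
      h$strand <- "-"
      pieces <- c(pieces, list(h))
    }
  }
  if (!length(pieces)) return(empty_hits())
  hits <- do.call(rbind, pieces)
  hits <- hits[order(hits$start, hits$strand, hits$length), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("start", "length", "strand")]), ,
               drop = FALSE]
  hits$sequence_id <- sequence_id
  hits$matched_text <- substring(seq, hits$start + 1L,
                                 hits$start + hits$length)
  rownames(hits) <- NULL
  hits <- hits[c("sequence_id", "start", "length", "strand", "spacers",
                 "mismatches", "matched_text")]
  if (!is.null(config$position_window)) {
    if (is.null(tss_scan_index))
      stop("position_window filtering needs tss_scan_index")
    lo <- config$position_window[1]; hi <- config$position_window[2]
    rs <- index_to_rel(hits$start, tss_scan_index)
    keep <- if (config$containment == "full") {
      re <- index_to_rel(hits$start + hits$length - 1L, tss_scan_index)
      rs >= lo & re <= hi
    } else rs >= lo & rs <= hi
    hits <- hits[keep, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Scan every promoter in a promoter set
#'
#' Applies [scan_sequence()] to each region and augments the hit table
#' with TSS-relative start/end coordinates (`rel_start`, `rel_end`, in
#' the no-zero coordinate system) and the gene id.
#'
#' @param promoters A `PromoterSet` (see [extract_promoters()] or
#'   [synthetic_promoters()]).
#' @param motif A [tandem_motif()].
#' @param config A [scan_config()].
#' @return Hit data frame; `sequence_id` is the transcript id.
#' @export
scan_promoters <- function(promoters, motif, config = scan_config()) {
  stopifnot(inherits(promoters, "PromoterSet"))
  tss <- promoters$tss_scan_index
  ids <- promoters$info$transcript_id
  res <- vector("list", length(promoters$sequences))
  for (i in seq_along(promoters$sequences)) {
    h <- scan_sequence(promoters$sequences[[i]], motif, config,
                       sequence_id = ids[i], tss_scan_index = tss)
    if (nrow(h)) res[[i]] <- h
  }
  res <- res[!vapply(res, is.null, logical(1))]
  hits <- if (length(res)) do.call(rbind, res) else empty_hits()
  hits$rel_start <- index_to_rel(hits$start, tss)
  hits$rel_end <- index_to_rel(hits$start + hits$length - 1L, tss)
  hits$gene_id <- promoters$info$gene_id[
    match(hits$sequence_id, promoters$info$transcript_id)]
  rownames(hits) <- NULL
  hits
}
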