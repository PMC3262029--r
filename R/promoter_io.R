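# TSS-relative coordinates follow the no-zero convention: +1 is the TSS
# base itself, -1 the base immediately upstream, positions increase in
# the direction of transcription. A -500..+500 window is 1000 bp with
# the TSS base at 0-based scan index 500.

#' Convert between TSS-relative coordinates and scan indices
#'
#' `rel_to_index()` maps a no-zero TSS-relative coordinate to the
#' 0-based index within an extracted window whose TSS base sits at
#' `tss_scan_index`; `index_to_rel()` is its inverse.  Both are
#' vectorized.
#'
#' @param rel Nonzero integer TSS-relative coordinate(s).
#' @param index 0-based scan index/indices.
#' @param tss_scan_index 0-based index of the TSS base (+1) within the
#'   window, or a `PromoterSet` from which it is taken.
#' @return Integer vector.
#' @examples
#' rel_to_index(c(-1, 1, 62), 500)
#' index_to_rel(c(499, 500, 561), 500)
#' @export
rel_to_index <- function(rel, tss_scan_index) {
  if (inherits(tss_scan_index, "PromoterSet"))
    tss_scan_index <- tss_scan_index$tss_scan_index
  rel <- as.integer(rel)
  if (anyNA(rel) || any(rel == 0L))
    stop("TSS-relative coordinates are nonzero integers (no-zero axis)")
  as.integer(tss_scan_index) + rel - (rel > 0L)
}

#' @rdname rel_to_index
#' @export
index_to_rel <- function(index, tss_scan_index) {
  if (inherits(tss_scan_index, "PromoterSet"))
    tss_scan_index <- tss_scan_index$tss_scan_index
  index <- as.integer(index)
  d <- index - as.integer(tss_scan_index)
  d + (d >= 0L)
}

#' Read a genome FASTA preserving masking
#'
#' Multi-line records, CRLF endings and mixed case are accepted;
#' identifiers are taken up to the first whitespace.  Lowercase
#' (soft-mask) and `N` (hard-mask) characters are preserved verbatim.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Parse transcript annotation into TSS records
#'
#' Reads GTF, GFF3 or BED6 and reduces each transcript feature to its
#' TSS: feature start for `+` features, feature end for `-` features;
#' BED intervals (0-based half-open) are converted to 1-based
#' coordinates.  Records without a strand are dropped with a warning.
#'
#' @param path Annotation file.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"bed"`.
#' @return Data frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `tss_genomic` (1-based).
#' @export
parse_annotation <- function(path, format = c("auto", "gtf", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff = "gff3", gff3 = "gff3",
                     bed = "bed",
                     stop("cannot infer annotation format from '.", ext,
                          "'; pass format="))
  }
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if (format %in% c("gtf", "gff3")) {
    if ("type" %in% names(mc)) {
      keep <- as.character(mc$type) %in%
        c("transcript", "mRNA", "gene", "ncRNA", "lnc_RNA")
      if (any(as.character(mc$type) %in% c("transcript", "mRNA")))
        keep <- as.character(mc$type) %in% c("transcript", "mRNA")
      gr <- gr[keep]
      mc <- S4Vectors::mcols(gr)
    }
    tid <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id)
           else if ("ID" %in% names(mc)) as.character(mc$ID)
           else paste0("tx", seq_along(gr))
    gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
           else if ("Parent" %in% names(mc))
             vapply(mc$Parent, function(p)
               if (length(p)) as.character(p[1]) else NA_character_,
               character(1))
           else tid
    gid[is.na(gid)] <- tid[is.na(gid)]
  } else {
    tid <- if ("name" %in% names(mc)) as.character(mc$name)
           else paste0("tx", seq_along(gr))
    gid <- tid
  }
  str <- as.character(BiocGenerics::strand(gr))
  nostrand <- !str %in% c("+", "-")
  if (any(nostrand)) {
    warning(sum(nostrand), " record(s) without strand dropped")
    gr <- gr[!nostrand]; str <- str[!nostrand]
    tid <- tid[!nostrand]; gid <- gid[!nostrand]
  }
  if (anyDuplicated(tid))
    stop("duplicate transcript ids in annotation: ",
         paste(unique(tid[duplicated(tid)])[1:3], collapse = ", "))
  tss <- ifelse(str == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
  data.frame(transcript_id = tid, gene_id = gid,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             strand = str, tss_genomic = as.integer(tss),
             stringsAsFactors = FALSE)
}

new_promoter_set <- function(sequences, info, upstream_rel, downstream_rel) {
  upstream_rel <- as.integer(upstream_rel)
  downstream_rel <- as.integer(downstream_rel)
  structure(list(
    sequences = sequences, info = info,
    upstream_rel = upstream_rel, downstream_rel = downstream_rel,
    tss_scan_index = if (upstream_rel < 0L) -upstream_rel
                     else 1L - upstream_rel,
    window_length = (if (upstream_rel < 0L) -upstream_rel
                     else 1L - upstream_rel) + downstream_rel),
    class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat("PromoterSet: ", length(x$sequences), " regions, window ",
      x$upstream_rel, "..+", x$downstream_rel, " (", x$window_length,
      " bp, TSS at scan index ", x$tss_scan_index, ")\n", sep = "")
  invisible(x)
}

#' Extract TSS-relative promoter windows
#'
#' Cuts the window `upstream_rel..downstream_rel` (no-zero coordinates;
#' e.g. -500..+500 gives 1000 bp with the TSS base at index 500, and
#' 1..200 gives the 200 bp from the TSS downstream) around each
#' transcript's TSS.  Minus-strand windows are reverse-complemented so
#' that index 0 is always the most upstream base and the sequence reads
#' 5'->3' in the direction of transcription.  Masking characters are
#' preserved verbatim.
#'
#' @param genome Named character vector (see [read_genome()]) or a path
#'   to a FASTA file.
#' @param annotations Data frame as returned by [parse_annotation()].
#' @param upstream_rel Upstream bound (<= -1), or a positive coordinate
#'   to start at/downstream of the TSS (e.g. 1 for TSS..+200).
#' @param downstream_rel Downstream bound (>= +1).
#' @param clip_policy Windows overrunning a contig edge are `"drop"`ped
#'   (with a message) or `"pad"`ded with `N` to full length.
#' @return A `PromoterSet`.
#' @export
extract_promoters <- function(genome, annotations,
                              upstream_rel = -500L, downstream_rel = 500L,
                              clip_policy = c("drop", "pad")) {
  clip_policy <- match.arg(clip_policy)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_genome(genome)
  upstream_rel <- as.integer(upstream_rel)
  downstream_rel <- as.integer(downstream_rel)
  if (upstream_rel == 0L || downstream_rel == 0L)
    stop("window bounds use no-zero coordinates")
  if (downstream_rel < 1L || upstream_rel > downstream_rel)
    stop("inverted window: need upstream_rel <= downstream_rel, ",
         "downstream_rel >= +1")
  missing_chrom <- setdiff(annotations$chrom, names(genome))
  if (length(missing_chrom))
    stop("chromosome(s) not in genome: ",
         paste(missing_chrom, collapse = ", "))
  # genomic 1-based offsets of the window's first/last base
  off_lo <- if (upstream_rel < 0L) upstream_rel else upstream_rel - 1L
  off_hi <- downstream_rel - 1L
  n <- nrow(annotations)
  seqs <- character(n); keep <- logical(n)
  for (i in seq_len(n)) {
    tss <- annotations$tss_genomic[i]
    clen <- nchar(genome[[annotations$chrom[i]]])
    if (annotations$strand[i] == "+") {
      g1 <- tss + off_lo; g2 <- tss + off_hi
    } else {
      g1 <- tss - off_hi; g2 <- tss - off_lo
    }
    if (g1 < 1L || g2 > clen) {
      if (clip_policy == "drop") {
        message("dropping ", annotations$transcript_id[i],
                ": window ", g1, "..", g2, " overruns contig ",
                annotations$chrom[i], " (1..", clen, ")")
        next
      }
      s <- substr(genome[[annotations$chrom[i]]], max(g1, 1L), min(g2, clen))
      s <- paste0(strrep("N", max(0L, 1L - g1)), s,
                  strrep("N", max(0L, g2 - clen)))
    } else {
      s <- substr(genome[[annotations$chrom[i]]], g1, g2)
    }
    if (annotations$strand[i] == "-") s <- reverse_complement(s)
    seqs[i] <- s; keep[i] <- TRUE
  }
  info <- annotations[keep, , drop = FALSE]
  rownames(info) <- NULL
  sequences <- setNames(seqs[keep], info$transcript_id)
  new_promoter_set(sequences, info, upstream_rel, downstream_rel)
}

#' Map promoter hits to genomic BED6 intervals
#'
#' Requires the promoter set to carry genomic provenance (chrom,
#' strand, genomic TSS).  Intervals are 0-based half-open; the BED
#' strand is the genomic strand of the matched motif (transcript strand
#' composed with hit strand); `name` is `sequence_id:motif_name` and
#' `score` the mismatch count.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param promoters The `PromoterSet` the hits came from.
#' @param motif_name Label used in the BED name column.
#' @return Data frame with BED6 columns `chrom`, `chromStart`,
#'   `chromEnd`, `name`, `score`, `strand`.
#' @export
hits_to_bed <- function(hits, promoters, motif_name = "motif") {
  stopifnot(inherits(promoters, "PromoterSet"))
  info <- promoters$info
  idx <- match(hits$sequence_id, info$transcript_id)
  if (anyNA(idx) || anyNA(info$chrom[idx]) || anyNA(info$tss_genomic[idx]))
    stop("hit(s) without genomic provenance")
  tx_strand <- info$strand[idx]
  tss <- info$tss_genomic[idx]
  up <- promoters$upstream_rel
  off0 <- if (up < 0L) up else up - 1L  # genomic offset of scan index 0
  i0 <- hits$start; i1 <- hits$start + hits$length - 1L
  g_start <- ifelse(tx_strand == "+", tss + off0 + i0, tss - off0 - i1)
  g_end   <- ifelse(tx_strand == "+", tss + off0 + i1, tss - off0 - i0)
  bed_strand <- ifelse(tx_strand == hits$strand, "+", "-")
  data.frame(chrom = info$chrom[idx],
             chromStart = as.integer(g_start - 1L),
             chromEnd = as.integer(g_end),
             name = paste0(hits$sequence_id, ":", motif_name),
             score = hits$mismatches,
             strand = bed_strand,
             stringsAsFactors = FALSE)
}

#' Write a BED6 data frame
#'
#' @param bed Data frame from [hits_to_bed()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a promoter set as FASTA plus sidecar TSV
#'
#' Headers take the form `>transcript_id|gene_id|window=-500..+500`;
#' the sidecar `<path>.tsv` holds the annotation columns.
#'
#' @param promoters A `PromoterSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(promoters, path) {
  win <- paste0("window=", promoters$upstream_rel, "..+",
                promoters$downstream_rel)
  hdr <- paste(promoters$info$transcript_id, promoters$info$gene_id,
               win, sep = "|")
  write_fasta(setNames(unname(promoters$sequences), hdr), path)
  write.table(promoters$info, paste0(path, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write or read a hit table as TSV
#'
#' Tab-separated with a `#`-prefixed header block carrying provenance
#' comments, followed by a column header line.
#'
#' @param hits Hit data frame.
#' @param path File path.
#' @param comments Character vector of provenance lines.
#' @return `path` (write) / hit data frame (read).
#' @export
write_hits_tsv <- function(hits, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(hits, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
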