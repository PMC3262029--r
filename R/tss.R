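# Reduction of TSS catalogs (CAGE-style tag clusters, cDNA-derived TSS
# tables) to representative TSSs, deduplication, and concordance of
# candidate annotations against a reference TSS set.

#' Representative TSS of a tag cluster
#'
#' The 5'-most tag of the cluster: minimum coordinate on the `+`
#' strand, maximum on `-`.  When several entries share the extreme
#' coordinate, ties break by highest tag count, then lowest coordinate
#' (a no-op for identical coordinates, kept for catalogs that list the
#' same position with different counts).
#'
#' @param positions 1-based tag coordinates (non-empty).
#' @param strand `"+"` or `"-"`.
#' @param counts Optional per-tag counts.
#' @return Single TSS coordinate.
#' @examples
#' cage_representative_tss(c(1005, 1000, 1010), "+")
#' @export
cage_representative_tss <- function(positions, strand, counts = NULL) {
  positions <- as.integer(positions)
  if (!length(positions) || anyNA(positions) || any(positions < 1L))
    stop("cluster must contain 1-based coordinates")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  extreme <- if (strand == "+") min(positions) else max(positions)
  at <- which(positions == extreme)
  if (length(at) > 1L && !is.null(counts))
    at <- at[order(-counts[at], positions[at])][1L]
  positions[at[1L]]
}

#' Deduplicate TSS records
#'
#' Keeps exactly one record per identical `(chrom, pos, strand)` triple
#' — the first in `(chrom, pos, strand, id)` sort order — replacing the
#' arbitrary choice of manual curation with a deterministic one.
#' Output is sorted; idempotent.
#'
#' @param records Data frame with columns `chrom`, `pos`, `strand` and
#'   optionally `id`.
#' @return List with `records` (deduplicated, sorted) and `n_removed`.
#' @export
dedup_tss <- function(records) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(records)))
  if (is.null(records$id)) records$id <- as.character(seq_len(nrow(records)))
  o <- order(records$chrom, records$pos, records$strand, records$id)
  records <- records[o, , drop = FALSE]
  key <- paste(records$chrom, records$pos, records$strand, sep = "\r")
  keep <- !duplicated(key)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_removed = sum(!keep))
}

#' Concordance of candidate TSS annotations with a reference
#'
#' For each reference gene with at least one candidate TSS, the
#' distance is the minimum absolute offset over its candidates
#' (candidates on a different chromosome or strand are ignored with a
#' warning); the summary mean is taken over covered genes and the
#' coverage fraction reports how many reference genes had any usable
#' candidate.
#'
#' @param reference Data frame `gene_id`, `tss` and optionally `chrom`,
#'   `strand`.
#' @param candidates Data frame `gene_id`, `tss` and optionally
#'   `chrom`, `strand` (checked only when present in both inputs).
#' @param signed Also report the signed offset of the closest
#'   candidate.
#' @return List with `per_gene` (gene_id, distance, signed_distance,
#'   n_candidates, covered), `mean_distance`, `coverage`.
#' @examples
#' closest_tss_concordance(
#'   data.frame(gene_id = c("g1", "g2"), tss = c(100, 200)),
#'   data.frame(gene_id = c("g1", "g1", "g2"), tss = c(90, 150, 205)))
#' @export
closest_tss_concordance <- function(reference, candidates, signed = FALSE) {
  stopifnot(nrow(reference) > 0,
            all(c("gene_id", "tss") %in% names(reference)),
            all(c("gene_id", "tss") %in% names(candidates)))
  check <- intersect(c("chrom", "strand"),
                     intersect(names(reference), names(candidates)))
  per <- data.frame(gene_id = reference$gene_id,
                    distance = NA_real_, signed_distance = NA_real_,
                    n_candidates = 0L, covered = FALSE,
                    stringsAsFactors = FALSE)
  n_mismatch <- 0L
  for (i in seq_len(nrow(reference))) {
    cand <- candidates[candidates$gene_id == reference$gene_id[i], ,
                       drop = FALSE]
    for (col in check) {
      bad <- cand[[col]] != reference[[col]][i]
      n_mismatch <- n_mismatch + sum(bad)
      cand <- cand[!bad, , drop = FALSE]
    }
    if (!nrow(cand)) next
    off <- cand$tss - reference$tss[i]
    j <- which.min(abs(off))
    per$distance[i] <- abs(off[j])
    per$signed_distance[i] <- off[j]
    per$n_candidates[i] <- nrow(cand)
    per$covered[i] <- TRUE
  }
  if (n_mismatch)
    warning(n_mismatch, " candidate(s) ignored for chrom/strand mismatch")
  if (!signed) per$signed_distance <- NULL
  list(per_gene = per,
       mean_distance = mean(per$distance[per$covered]),
       coverage = mean(per$covered))
}
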