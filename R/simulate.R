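# Synthetic promoter generator: background-sampled windows with motif
# instances planted at controlled TSS-relative positions and strands,
# plus soft-mask planting. A single root seed spawns one deterministic
# sub-stream per promoter, so any subset of promoters is reproducible
# on its own.

sample_background_chars <- function(n, background) {
  bases <- c("A", "C", "G", "T")
  if (background$order == 0L)
    return(sample(bases, n, replace = TRUE, prob = background$freqs))
  out <- character(n)
  out[1] <- sample(bases, 1L, prob = background$start)
  for (i in seq_len(n - 1L))
    out[i + 1L] <- sample(bases, 1L, prob = background$trans[out[i], ])
  out
}

sample_motif_instance <- function(motif, background) {
  spacers <- vapply(motif$spacer_ranges,
                    function(r) if (r[1] == r[2]) r[1]
                                else sample(seq.int(r[1], r[2]), 1L),
                    integer(1))
  parts <- character(2L * length(motif$flanks) - 1L)
  parts[seq_along(motif$flanks) * 2L - 1L] <- motif$flanks
  for (j in seq_along(spacers))
    parts[2L * j] <- paste(sample_background_chars(spacers[j], background),
                           collapse = "")
  list(text = paste(parts, collapse = ""), spacers = spacers)
}

#' Generate synthetic promoters with planted motif instances
#'
#' Sequences are sampled from the background model; in a
#' `plant_fraction` of promoters one motif instance (exact flanks,
#' spacer bases refilled from the background so planted instances do
#' not distort composition estimates) overwrites the window at the
#' drawn TSS-relative position and strand.  Minus-strand instances are
#' written as the reverse complement of a sampled instance; the planted
#' position is always the leftmost sense-strand base, i.e. the `start`
#' a scan reports.  Fully reproducible from `seed`.
#'
#' @param n_promoters Number of promoter windows.
#' @param upstream_rel,downstream_rel Window bounds (no-zero axis).
#' @param background A `BackgroundModel`.
#' @param plant_fraction Fraction of promoters receiving an instance.
#' @param plant_position Candidate TSS-relative start position(s) of
#'   planted instances (default +62, the canonical location).
#' @param plant_position_weights Optional sampling weights over
#'   `plant_position`.
#' @param plant_strand_prob Probability that a planted instance is on
#'   the forward (sense) strand.
#' @param motif A [tandem_motif()].
#' @param transcripts_per_gene Consecutive transcripts grouped under
#'   one gene id (for gene-collapse tests).
#' @param seed Integer root seed.
#' @return List with `promoters` (a `PromoterSet` without genomic
#'   provenance) and `truth` (one row per promoter: `transcript_id`,
#'   `gene_id`, `planted`, `position`, `strand`, `spacers`).
#' @examples
#' sim <- synthetic_promoters(5, plant_fraction = 1, seed = 42)
#' sim$truth
#' @export
synthetic_promoters <- function(n_promoters,
                                upstream_rel = -500L, downstream_rel = 500L,
                                background = uniform_background(),
                                plant_fraction = 0,
                                plant_position = 62L,
                                plant_position_weights = NULL,
                                plant_strand_prob = 1,
                                motif = ltsm_motif(),
                                transcripts_per_gene = 1L,
                                seed = 1L) {
  upstream_rel <- as.integer(upstream_rel)
  downstream_rel <- as.integer(downstream_rel)
  tssi <- if (upstream_rel < 0L) -upstream_rel else 1L - upstream_rel
  Lwin <- (if (upstream_rel < 0L) -upstream_rel
           else 1L - upstream_rel) + downstream_rel
  maxlen <- motif_max_length(motif)
  if (plant_fraction > 0) for (p in plant_position) {
    idx <- rel_to_index(p, tssi)
    if (idx < 0L || idx + maxlen > Lwin)
      stop("plant position ", p, " cannot host a ", maxlen,
           "-bp instance inside the window")
  }
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_promoters)
  wd <- max(4L, nchar(n_promoters))
  tx_ids <- sprintf(paste0("T%0", wd, "d"), seq_len(n_promoters))
  gene_ids <- sprintf(paste0("G%0", wd, "d"),
                      (seq_len(n_promoters) - 1L) %/%
                        as.integer(transcripts_per_gene) + 1L)
  seqs <- character(n_promoters)
  truth <- data.frame(transcript_id = tx_ids, gene_id = gene_ids,
                      planted = FALSE, position = NA_integer_,
                      strand = NA_character_, spacers = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_promoters)) {
    set.seed(sub_seeds[i])
    ch <- sample_background_chars(Lwin, background)
    if (runif(1) < plant_fraction) {
      pos <- if (length(plant_position) == 1L) plant_position[1]
             else sample(plant_position, 1L, prob = plant_position_weights)
      fwd <- runif(1) < plant_strand_prob
      inst <- sample_motif_instance(motif, background)
      txt <- if (fwd) inst$text else reverse_complement(inst$text)
      idx <- rel_to_index(pos, tssi)
      ch[seq_len(nchar(txt)) + idx] <- strsplit(txt, "", fixed = TRUE)[[1]]
      truth$planted[i] <- TRUE
      truth$position[i] <- as.integer(pos)
      truth$strand[i] <- if (fwd) "+" else "-"
      truth$spacers[i] <- paste(inst$spacers, collapse = ",")
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  info <- data.frame(transcript_id = tx_ids, gene_id = gene_ids,
                     chrom = NA_character_, strand = NA_character_,
                     tss_genomic = NA_integer_, stringsAsFactors = FALSE)
  list(promoters = new_promoter_set(setNames(seqs, tx_ids), info,
                                    upstream_rel, downstream_rel),
       truth = truth)
}

#' Soft-mask a sequence interval
#'
#' Lowercases the 1-based inclusive interval, leaving content
#' unchanged.
#'
#' @param seq DNA string.
#' @param start,end 1-based inclusive bounds.
#' @return Masked sequence.
#' @export
apply_mask <- function(seq, start, end) {
  stopifnot(start >= 1L, end <= nchar(seq), start <= end)
  paste0(substr(seq, 1L, start - 1L),
         tolower(substr(seq, start, end)),
         substr(seq, end + 1L, nchar(seq)))
}

#' Plant soft-masked stretches into sequences
#'
#' Lowercases non-overlapping random stretches until the requested mask
#' fraction is reached (within sampling tolerance), emulating
#' repeat-masked promoter sets.  Content is unchanged; a truth table of
#' masked intervals is returned.
#'
#' @param sequences Character vector of DNA strings.
#' @param mask_fraction Target fraction of masked bases per sequence.
#' @param stretch_length `c(min, max)` stretch length range in bp.
#' @param seed Integer seed.
#' @return List with `sequences` (masked) and `mask_truth` (data frame
#'   `sequence`, `start`, `end`, 1-based inclusive).
#' @export
plant_masked_repeats <- function(sequences, mask_fraction = 0.1,
                                 stretch_length = c(20L, 200L),
                                 seed = 1L) {
  stopifnot(mask_fraction >= 0, mask_fraction <= 1,
            all(stretch_length >= 1L))
  set.seed(seed)
  rows <- list()
  out <- sequences
  for (i in seq_along(sequences)) {
    L <- nchar(sequences[i])
    target <- round(mask_fraction * L)
    masked <- 0L
    taken <- logical(L)
    attempts <- 0L
    while (masked < target && attempts < 500L) {
      attempts <- attempts + 1L
      len <- sample(seq.int(stretch_length[1],
                            min(stretch_length[2], L)), 1L)
      if (len > target - masked + stretch_length[1]) len <-
        max(stretch_length[1], target - masked)
      s <- sample.int(L - len + 1L, 1L)
      if (any(taken[s:(s + len - 1L)])) next
      taken[s:(s + len - 1L)] <- TRUE
      out[i] <- apply_mask(out[i], s, s + len - 1L)
      rows[[length(rows) + 1L]] <- data.frame(sequence = i, start = s,
                                              end = s + len - 1L)
      masked <- masked + len
    }
  }
  mask_truth <- if (length(rows)) do.call(rbind, rows)
                else data.frame(sequence = integer(), start = integer(),
                                end = integer())
  list(sequences = out, mask_truth = mask_truth)
}

#' Synthetic ribosomal-protein-style promoter panel
#'
#' A fully synthetic benchmark panel of 81 promoter windows
#' (-500..+500) that emulates the canonical positional composition
#' reported for the human ribosomal protein promoter set: 50 canonical
#' ATC-7-ATC instances in total — 35 on the sense strand starting
#' inside the preferred window +52..+82, 2 sense-strand instances
#' elsewhere, 13 on the reverse-complement strand at scattered
#' positions — plus tripartite ATC-8-ATC-6-ATC instances at the typical
#' location in the four promoters named after the genes known to carry
#' them (RPS15A, RPL17, RPL3, RPS24).  The background is drawn from
#' \{A, G\} only and planted spacers are filled with `A`, which makes
#' chance ATC or GAT matches impossible: scanning recovers exactly the
#' planted composition.  This panel is synthetic stand-in data for
#' validating the scan/classify/collapse pipeline, not the published
#' hit table.
#'
#' @param seed Integer seed for the background sampling.
#' @return List with `promoters` (a `PromoterSet`) and `truth` (planted
#'   instance table: `transcript_id`, `gene_id`, `motif`, `position`,
#'   `strand`).
#' @export
rp_like_promoter_panel <- function(seed = 1L) {
  n <- 81L
  tripartite_genes <- c("RPS15A", "RPL17", "RPL3", "RPS24")
  gene_ids <- c(sprintf("RPG%02d", 1:50), tripartite_genes,
                sprintf("RPG%02d", 55:81))
  tx_ids <- paste0(gene_ids, ".t1")
  upstream <- -500L; downstream <- 500L
  tssi <- 500L; Lwin <- 1000L
  ag_background <- structure(
    list(order = 0L, freqs = c(A = .5, C = 0, G = .5, T = 0)),
    class = "BackgroundModel")
  # planted composition: position (rel start) and strand per promoter
  plan <- data.frame(i = 1:54,
                     motif = c(rep("canonical", 50), rep("tripartite", 4)),
                     position = c(52L + (0:34) %% 31L,      # 35 preferred fwd
                                  -100L, 200L,              # 2 elsewhere fwd
                                  as.integer(seq(-450, 430, length.out = 13)),
                                  rep(58L, 4)),             # tripartite
                     strand = c(rep("+", 37), rep("-", 13), rep("+", 4)),
                     stringsAsFactors = FALSE)
  plan$position[plan$position == 0L] <- 5L
  canonical <- "ATCAAAAAAAATC"
  tripart <- "ATCAAAAAAAAATCAAAAAAATC"
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    ch <- sample_background_chars(Lwin, ag_background)
    row <- plan[plan$i == i, ]
    if (nrow(row)) {
      txt <- if (row$motif == "canonical") canonical else tripart
      if (row$strand == "-") txt <- reverse_complement(txt)
      idx <- rel_to_index(row$position, tssi)
      ch[seq_len(nchar(txt)) + idx] <- strsplit(txt, "", fixed = TRUE)[[1]]
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  info <- data.frame(transcript_id = tx_ids, gene_id = gene_ids,
                     chrom = NA_character_, strand = NA_character_,
                     tss_genomic = NA_integer_, stringsAsFactors = FALSE)
  truth <- data.frame(transcript_id = tx_ids[plan$i],
                      gene_id = gene_ids[plan$i],
                      motif = plan$motif, position = plan$position,
                      strand = plan$strand, stringsAsFactors = FALSE)
  list(promoters = new_promoter_set(setNames(seqs, tx_ids), info,
                                    upstream, downstream),
       truth = truth)
}
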