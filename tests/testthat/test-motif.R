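test_that("tandem_motif validates its geometry", {
  m <- tandem_motif(c("ATC", "ATC"), list(c(7, 7)))
  expect_s3_class(m, "TandemMotif")
  expect_equal(motif_min_length(m), 13L)
  expect_equal(motif_max_length(m), 13L)
  expect_equal(motif_min_length(ltsm_tripartite_motif()), 23L)
  expect_error(tandem_motif("ATC", list()), "at least 2 flanks")
  expect_error(tandem_motif(c("ATC", "AXC"), list(c(7, 7))), "A,C,G,T")
  expect_error(tandem_motif(c("ATC", "ATC"), list(c(8, 7))), "min <= max")
  expect_error(tandem_motif(c("ATC", "ATC"), list(c(7, 7), c(6, 6))),
               "one spacer range per gap")
})

test_that("flank offsets give the one-helical-turn T-to-T spacing", {
  offs <- flank_offsets(ltsm_motif(), 7)
  expect_equal(offs, c(0L, 10L))
  # the T sits at the second flank base: T positions 1 and 11, 10 bp apart
  t_pos <- offs + 1L
  expect_equal(diff(t_pos), 10L)
  expect_equal(flank_offsets(ltsm_tripartite_motif(), c(8, 6)),
               c(0L, 11L, 20L))
  expect_error(flank_offsets(ltsm_motif(), 6), "outside allowed range")
})

test_that("reverse_complement preserves case and N and is an involution", {
  expect_identical(reverse_complement("ATC"), "GAT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("aTgN"), "NcAt")
  expect_error(reverse_complement("ATX"), "'X' at position 3")
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N", "n"),
                      50, replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("match_at applies mismatch budget and mask policy", {
  m <- ltsm_motif()
  h <- match_at("ATCAAAAAAAATC", 0, m, 7)
  expect_equal(h$length, 13L)
  expect_equal(h$mismatches, 0L)
  expect_null(match_at("ATCAAAAAAAACC", 0, m, 7, max_mismatch = 0))
  h1 <- match_at("ATCAAAAAAAACC", 0, m, 7, max_mismatch = 1)
  expect_equal(h1$mismatches, 1L)
  # lowercase only in the spacer: suppressed under skip_masked only
  expect_null(match_at("ATCAAAaAAAATC", 0, m, 7,
                       mask_policy = "skip_masked"))
  expect_equal(match_at("ATCAAAaAAAATC", 0, m, 7)$mismatches, 0L)
  # an N on a flank position kills the match even with budget left
  expect_null(match_at("NTCAAAAAAAATC", 0, m, 7, max_mismatch = 5))
  # but an N in the spacer is fine under ignore_mask
  expect_equal(match_at("ATCAAANAAAATC", 0, m, 7)$mismatches, 0L)
  expect_error(match_at("ATCAAAAAAAATC", 1, m, 7), "out of range")
})

test_that("scan_sequence finds constructed bipartite hits on both strands", {
  hits <- scan_sequence("GGATCGGGGGGGATCGG", ltsm_motif())
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$start, 2L)
  expect_equal(fwd$spacers, "7")
  expect_equal(fwd$matched_text, "ATCGGGGGGGATC")
  # the same 17-mer also carries a genuine reverse-strand pairing
  rev_ <- hits[hits$strand == "-", ]
  expect_equal(rev_$start, 1L)
  expect_match(reverse_complement(rev_$matched_text), "^ATC.{7}ATC$")

  hits2 <- scan_sequence("TTGATCCCCCCCGATTT", ltsm_motif())
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$length, 13L)
  # verified by the rc-and-rescan oracle: start maps to n - s_rc - L
  expect_equal(hits2$start, 2L)
  expect_match(reverse_complement(hits2$matched_text), "^ATC.{7}ATC$")
})

test_that("a tripartite motif is just a 3-flank tandem scan", {
  s <- "ATCAAAAAAAAATCAAAAAAATC"
  expect_equal(nchar(s), 23L)
  h <- scan_sequence(s, ltsm_tripartite_motif(), scan_config("forward"))
  expect_equal(h$start, 0L)
  expect_equal(h$spacers, "8,6")
  # no 7-bp gap exists between any ATC pair
  expect_equal(nrow(scan_sequence(s, ltsm_motif())), 0L)
  # the spacer-8 and spacer-6 bipartite variants each find one hit
  expect_equal(nrow(scan_sequence(s, ltsm_variant_motif(8),
                                  scan_config("forward"))), 1L)
  expect_equal(nrow(scan_sequence(s, ltsm_variant_motif(6),
                                  scan_config("forward"))), 1L)
})

test_that("short or empty-hit sequences return an empty frame, not an error", {
  expect_equal(nrow(scan_sequence("ATC", ltsm_motif())), 0L)
  expect_error(scan_sequence("", ltsm_motif()), "non-empty")
  expect_error(scan_sequence("ATCQ", ltsm_motif()), "'Q' at position 4")
})

test_that("scanning agrees with the brute-force oracle on random sequences", {
  motif <- tandem_motif(c("ATC", "ATC"), list(c(6, 8)), "ltsm-6to8")
  set.seed(11)
  for (rep in 1:25) {
    s <- random_dna(400)
    for (mm in 0:1) {
      hits <- scan_sequence(s, motif, scan_config(max_mismatch = mm))
      expect_hits_equal_oracle(hits, oracle_scan(s, motif, mm))
    }
  }
})

test_that("strand symmetry maps hits through the reverse complement", {
  set.seed(13)
  for (rep in 1:10) {
    s <- random_dna(300)
    n <- nchar(s)
    fwd_on_rc <- scan_sequence(reverse_complement(s), ltsm_motif(),
                               scan_config("forward", max_mismatch = 1))
    rev_on_s <- scan_sequence(s, ltsm_motif(),
                              scan_config("reverse", max_mismatch = 1))
    mapped <- sort(n - fwd_on_rc$start - fwd_on_rc$length)
    expect_equal(sort(rev_on_s$start), mapped)
  }
})

test_that("hit sets are monotone in the mismatch budget and deterministic", {
  set.seed(17)
  s <- random_dna(800)
  key <- function(h) paste(h$start, h$length, h$strand)
  h0 <- scan_sequence(s, ltsm_motif(), scan_config(max_mismatch = 0))
  h1 <- scan_sequence(s, ltsm_motif(), scan_config(max_mismatch = 1))
  h2 <- scan_sequence(s, ltsm_motif(), scan_config(max_mismatch = 2))
  expect_true(all(key(h0) %in% key(h1)))
  expect_true(all(key(h1) %in% key(h2)))
  expect_identical(h2, scan_sequence(s, ltsm_motif(),
                                     scan_config(max_mismatch = 2)))
  # ordering contract: ascending start, '+' before '-' at equal start
  expect_true(!is.unsorted(h2$start))
  ties <- split(h2$strand, h2$start)
  for (tt in ties) expect_true(!is.unsorted(match(tt, c("+", "-"))))
})

test_that("mask policies reproduce the masked/unmasked scan contrast", {
  s <- "ATCAAAaAAAATC"
  expect_equal(nrow(scan_sequence(s, ltsm_motif(),
                                  scan_config("forward",
                                              mask_policy = "skip_masked"))),
               0L)
  expect_equal(scan_sequence(s, ltsm_motif(),
                             scan_config("forward"))$start, 0L)
  # fully lowercased instance still matches case-insensitively
  expect_equal(nrow(scan_sequence(tolower(s), ltsm_motif(),
                                  scan_config("forward"))), 1L)
})

test_that("position_window restricts hits by containment rule", {
  # promoter-like sequence with TSS index 100, hit starting at rel +90
  s <- paste0(strrep("G", 189), "ATCAAAAAAAATC", strrep("G", 98))
  cfg_full <- scan_config("forward", position_window = c(21, 100))
  cfg_start <- scan_config("forward", position_window = c(21, 100),
                           containment = "start_only")
  expect_equal(nrow(scan_sequence(s, ltsm_motif(), cfg_full,
                                  tss_scan_index = 100)), 0L)
  expect_equal(nrow(scan_sequence(s, ltsm_motif(), cfg_start,
                                  tss_scan_index = 100)), 1L)
  expect_error(scan_sequence(s, ltsm_motif(), cfg_full),
               "tss_scan_index")
})
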