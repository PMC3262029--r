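test_that("background estimation applies pseudo-counts and masking", {
  b <- estimate_background("ACGT")
  expect_equal(unname(b$freqs), rep(2 / 8, 4))
  b2 <- estimate_background(c("AAAA", "TTTT"))
  expect_equal(unname(b2$freqs[c("A", "T")]), c(5 / 12, 5 / 12))
  expect_equal(unname(b2$freqs[c("C", "G")]), c(1 / 12, 1 / 12))
  # masked bases excluded: N always, lowercase under skip_masked
  b3 <- estimate_background("AAAANNNN")
  expect_equal(unname(b3$freqs["A"]), 5 / 8)
  b4 <- estimate_background("AAAAcccc", mask_policy = "skip_masked")
  expect_equal(unname(b4$freqs["A"]), 5 / 8)
  b5 <- estimate_background("AAAAcccc")
  expect_equal(unname(b5$freqs["A"]), 5 / 12)
})

test_that("estimated frequencies converge on the truth in simulation", {
  set.seed(43)
  truth <- c(A = .4, C = .15, G = .15, T = .3)
  s <- random_dna(10000, truth)
  b <- estimate_background(s)
  se <- sqrt(truth * (1 - truth) / 10000)
  expect_true(all(abs(b$freqs - truth) < 3 * se + 1e-3))
  # order-1 fit on i.i.d. data: rows near the marginal
  b1 <- estimate_background(s, order = 1)
  expect_true(all(abs(t(b1$trans) - truth) < 0.05))
  expect_equal(sum(b1$start), 1)
})

test_that("motif probabilities follow the closed forms", {
  expect_equal(motif_probability(ltsm_motif(), 7, uniform_background()),
               (1 / 4)^6)
  expect_equal(motif_probability(ltsm_motif(), 7, gc_background(0.6)),
               (0.2 * 0.2 * 0.3)^2)
  # order-1 with an i.i.d.-equivalent chain reduces to the product form
  bases <- c("A", "C", "G", "T")
  f <- c(A = .3, C = .2, G = .2, T = .3)
  b1 <- structure(list(order = 1L, freqs = f,
                       trans = matrix(rep(f, each = 4), 4,
                                      dimnames = list(bases, bases)),
                       start = f), class = "BackgroundModel")
  expect_equal(motif_probability(ltsm_motif(), 7, b1),
               (f[["A"]] * f[["T"]] * f[["C"]])^2)
})

test_that("motif probability matches Monte-Carlo match frequency", {
  set.seed(47)
  bg <- gc_background(0.6)
  n_draw <- 200000L
  p <- motif_probability(ltsm_motif(), 7, bg)
  draws <- matrix(sample(c("A", "C", "G", "T"), 13 * n_draw,
                         replace = TRUE, prob = bg$freqs), nrow = 13)
  ok <- draws[1, ] == "A" & draws[2, ] == "T" & draws[3, ] == "C" &
    draws[11, ] == "A" & draws[12, ] == "T" & draws[13, ] == "C"
  se <- sqrt(p * (1 - p) / n_draw)
  expect_lt(abs(mean(ok) - p), 3 * se)
})

test_that("expected hit counts follow the positional arithmetic", {
  expect_equal(expected_hits(1000, ltsm_motif(), scan_config("forward")),
               988 * 4^-6)
  expect_equal(expected_hits(1000, ltsm_motif(), scan_config("both")),
               2 * 988 * 4^-6)
  m68 <- tandem_motif(c("ATC", "ATC"), list(c(6, 8)))
  expect_equal(expected_hits(1000, m68, scan_config("forward")),
               (989 + 988 + 987) * 4^-6)
  # additive over disjoint windows (up to boundary effects the spec's
  # formula charges per window)
  expect_lt(expected_hits(400, ltsm_motif(), scan_config("forward")) +
              expected_hits(600, ltsm_motif(), scan_config("forward")),
            expected_hits(1000, ltsm_motif(), scan_config("forward")))
  # strand asymmetry under a skewed background
  bg <- structure(list(order = 0L,
                       freqs = c(A = .5, C = .3, G = .1, T = .1)),
                  class = "BackgroundModel")
  fwd <- expected_hits(1000, ltsm_motif(), scan_config("forward"), bg)
  rev_ <- expected_hits(1000, ltsm_motif(), scan_config("reverse"), bg)
  expect_equal(fwd, 988 * (.5 * .1 * .3)^2)
  expect_equal(rev_, 988 * (.1 * .5 * .1)^2)  # GAT content
  expect_equal(expected_hits(1000, ltsm_motif(), scan_config("both"), bg),
               fwd + rev_)
})

test_that("per-bin Poisson tails match the partial-sum oracle", {
  hits <- data.frame(sequence_id = "t", rel_start = rep(30L, 5),
                     strand = "+")
  h <- build_histogram(hits, c(-500, 500), 20, 1000)
  enr <- bin_enrichment(h, ltsm_motif(), uniform_background(), "forward")
  row <- enr[enr$bin_lo == 21, ]
  expect_equal(row$expected, 1000 * 20 * 4^-6)
  expect_equal(row$p, poisson_tail_reference(5, row$expected),
               tolerance = 1e-12)
  expect_equal(enr$p[enr$observed_fwd == 0], rep(1, sum(enr$observed_fwd == 0)))
  # expectation accounts for infeasible starts at the window edge
  last <- enr[nrow(enr), ]
  expect_equal(last$expected, 1000 * (20 - 12) * 4^-6)
  # BH column equals the reference step-up on the same p's
  expect_equal(enr$q, bh_reference(enr$p), tolerance = 1e-12)
})

test_that("Fisher's exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)),
               1 / 3, tolerance = 1e-12)
  tab <- matrix(c(26, 21, 9, 25), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab), fisher_reference(26, 21, 9, 25),
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(tab),
               stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("Fisher p is invariant under simultaneous row and column swap", {
  set.seed(53)
  for (i in 1:50) {
    x <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (min(rowSums(x), colSums(x)) == 0) next
    swapped <- x[2:1, 2:1]
    expect_equal(fisher_exact_2x2(x), fisher_exact_2x2(swapped),
                 tolerance = 1e-12)
    expect_gt(fisher_exact_2x2(x), 0)
    expect_lte(fisher_exact_2x2(x), 1)
  }
})

test_that("BH adjustment equals the literal step-up reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(59)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_reference(p), tolerance = 1e-12)
    o <- order(p)
    expect_true(!is.unsorted(q[o]))
    expect_equal(q[o][length(p)], p[o][length(p)])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("set overlap test matches hypergeometric enumeration", {
  r <- set_overlap_test(c("g1", "g2"), c("g2", "g3"), 10)
  expect_equal(r$overlap, 1L)
  r2 <- set_overlap_test(c("a", "b"), c("c", "d"), 20)
  expect_equal(r2$overlap, 0L)
  expect_equal(r2$p, 1)
  # small-instance enumeration of the hypergeometric mass
  enum_p <- function(U, nA, nB, k) {
    ks <- max(0, nA + nB - U):min(nA, nB)
    mass <- choose(nA, ks) * choose(U - nA, nB - ks) / choose(U, nB)
    sum(mass[ks >= k])
  }
  set.seed(61)
  for (i in 1:30) {
    U <- sample(5:30, 1)
    A <- sample(paste0("g", 1:U), sample(1:U, 1))
    B <- sample(paste0("g", 1:U), sample(1:U, 1))
    r <- set_overlap_test(A, B, U)
    expect_equal(r$p, enum_p(U, length(A), length(B), r$overlap),
                 tolerance = 1e-12)
  }
  expect_error(set_overlap_test(c("a", "b"), "c", 2), "universe")
})

test_that("null simulation p-values are calibrated at small scale", {
  sim <- synthetic_promoters(2000, plant_fraction = 0, seed = 67)
  hits <- scan_promoters(sim$promoters, ltsm_motif(), scan_config("forward"))
  h <- build_histogram(hits, c(-500, 500), 20, 2000)
  enr <- bin_enrichment(h, ltsm_motif(), uniform_background(), "forward")
  # upper-tail p-values under the null are (super)uniform: the fraction
  # below 0.05 stays within generous binomial bounds of 0.05
  frac <- mean(enr$p < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(enr)))
})
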