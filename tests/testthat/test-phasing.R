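test_that("register arithmetic matches the stated convention", {
  expect_equal(register_of(42, 21, "+", 21), 0)
  expect_equal(register_of(0, 24, "+", 24), 0)
  expect_equal(register_of(100, 21, "+", 21), 100 %% 21)
  # minus read register uses the half-open right edge + 2
  expect_equal(register_of(98, 21, "-", 21), (98 + 21 + 2) %% 21)
})

test_that("both strands of a perfect 2-nt 3'-overhang duplex share one register", {
  for (s in c(21, 24)) {
    for (p in 0:(s - 1)) {
      plus <- register_of(p, s, "+", s)
      # duplex partner spans [p - 2, p - 2 + s)
      minus <- register_of(p - 2, s, "-", s)
      expect_identical(minus %% s, plus)
      expect_equal(phase_coordinate(p - 2, s, "-", s), p)
    }
  }
})

test_that("register profiles tally abundance and break ties to the smallest index", {
  lib <- make_library(start = c(100, 121, 142, 103), length = 21,
                      strand = "+", count = c(30, 25, 15, 30),
                      total_primary = 1e6)
  locus <- list(chrom = "chr1", start = 90, end = 200)
  p <- register_profile(lib, locus, 21)
  expect_equal(p$dominant_register, 100 %% 21)
  expect_equal(p$dominant_fraction, 70 / 100)
  expect_equal(sum(p$register_abundance), 100)

  # uniform over all 21 registers -> dominant fraction 1/21, tie flagged
  u <- make_library(start = 100 + 0:20, length = 21, strand = "+",
                    count = 1, total_primary = 1e6)
  pu <- register_profile(u, list(chrom = "chr1", start = 0, end = 300), 21)
  expect_equal(pu$dominant_fraction, 1 / 21)
  expect_true(pu$tied)

  # no eligible reads -> empty profile
  pe <- register_profile(u, list(chrom = "chr1", start = 1000, end = 1100), 21)
  expect_equal(pe$dominant_fraction, 0)
  expect_true(is.na(pe$dominant_register))
})

test_that("log-odds kernel reproduces hand-computed values and its guards", {
  expect_equal(phase_logodds_score(100, 0, 9), 7 * log(1001), tolerance = 1e-12)
  expect_equal(phase_logodds_score(50, 10, 2), 0)
  expect_equal(phase_logodds_score(0, 5, 7), 0, tolerance = 1e-12)
})

test_that("log-odds kernel is monotone in P and U", {
  P <- seq(0, 200, by = 10)
  for (U in c(0, 5, 50)) {
    for (k in 3:9) {
      sc <- phase_logodds_score(P, U, k)
      expect_true(all(diff(sc) >= 0))
    }
  }
  U <- seq(0, 200, by = 10)
  for (k in 3:9) {
    sc <- phase_logodds_score(100, U, k)
    expect_true(all(diff(sc) <= 0))
  }
})

test_that("hypergeometric tail matches subset enumeration on spot checks", {
  # N = 42, K = 2, n = 4: full enumeration over all C(42, 4) subsets
  enum <- enum_hypergeom_tail(42, 2, 4)
  for (x in 0:2) {
    expect_equal(hypergeom_tail(x, 42, 2, 4), unname(enum[x + 1]),
                 tolerance = 1e-12)
  }
  # closed form of the x = 2 tail: C(2,2) C(40,2) / C(42,4)
  expect_equal(hypergeom_tail(2, 42, 2, 4),
               choose(40, 2) / choose(42, 4), tolerance = 1e-15)
})

test_that("windowed hypergeometric p-value honors its degenerate cases", {
  locus <- list(chrom = "chr1", start = 0, end = 210)
  empty <- make_library(5000, 21, "+", total_primary = 1e6)
  expect_equal(phase_hypergeom(empty, locus, 21, m = 10)$pval, 1)

  # every strand-collapsed position occupied -> x forced to K -> p = 1
  full <- make_library(start = 0:209, length = 21, strand = "+",
                       count = 1, total_primary = 1e6)
  expect_equal(phase_hypergeom(full, locus, 21, m = 10)$pval, 1)
})

test_that("phased-ratio score matches hand evaluation", {
  # perfectly phased, 9 occupied cycles -> ratio 9
  lib <- make_phased_library(trigger = 105, s = 21, n_cycles = 9,
                             both_strands = FALSE, total_primary = 1e6)
  locus <- list(chrom = "chr1", start = 100, end = 100 + 9 * 21 + 10)
  expect_equal(phase_ratio(lib, locus, 21, m = 9)$score, 9)

  # P = U with 4 occupied in-register cycles -> 0.5 * 4 = 2
  lib2 <- make_library(start = c(105, 126, 147, 168, 110),
                       length = 21, strand = "+",
                       count = c(10, 10, 10, 10, 40), total_primary = 1e6)
  locus2 <- list(chrom = "chr1", start = 105, end = 105 + 4 * 21)
  expect_equal(phase_ratio(lib2, locus2, 21, m = 4)$score, 2)

  # empty window -> 0
  expect_equal(phase_ratio(make_library(9000, 21, "+", total_primary = 1e6),
                           locus2, 21, m = 4)$score, 0)
})

test_that("all three statistics are invariant under translation by multiples of s", {
  set.seed(11)
  s <- 21
  start <- sort(sample(100:500, 40, replace = TRUE))
  lib <- make_library(start = start, length = s,
                      strand = sample(c("+", "-"), 40, TRUE),
                      count = sample(1:10, 40, TRUE), total_primary = 1e6)
  locus <- list(chrom = "chr1", start = 80, end = 560)
  base <- phase_locus(lib, locus, s)
  for (t in c(1, 4, 10)) {
    r <- lib$reads
    r$start <- r$start + t * s
    shifted <- srna_library(r, total_primary = 1e6)
    locus_t <- list(chrom = "chr1", start = 80 + t * s, end = 560 + t * s)
    sh <- phase_locus(shifted, locus_t, s)
    expect_equal(sh$score_logodds, base$score_logodds, tolerance = 1e-12)
    expect_equal(sh$pval_hypergeom, base$pval_hypergeom, tolerance = 1e-12)
    expect_equal(sh$score_ratio, base$score_ratio, tolerance = 1e-12)
  }
})

test_that("per-register null p-values are conservative (stochastically >= uniform)", {
  set.seed(202)
  s <- 24; m <- 10; N <- m * s
  pvals <- replicate(400, {
    # uniform occupancy of one window
    n <- 20
    coords <- sample(0:(N - 1), n)
    x <- sum(coords %% s == 0)
    hypergeom_tail(x, N, m, n)
  })
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(quantile(pvals, qs) >= qs - 0.08))
})

test_that("register consistency separates phased loci from uniform noise", {
  libs <- lapply(1:4, function(j) {
    make_phased_library(trigger = 100, s = 21, n_cycles = 10, count = 3,
                        library_id = paste0("lib", j), total_primary = 1e6)
  })
  locus <- list(chrom = "chr1", start = 90, end = 330)
  rc <- register_consistency(locus, libs, 21)
  expect_true(rc$consistent)
  expect_true(rc$majority)
  expect_equal(rc$min_dominant_fraction, 1)

  set.seed(5)
  noisy <- lapply(1:4, function(j) {
    make_library(start = sample(90:300, 60, TRUE), length = 21,
                 strand = sample(c("+", "-"), 60, TRUE),
                 library_id = paste0("lib", j), total_primary = 1e6)
  })
  rn <- register_consistency(locus, noisy, 21)
  expect_false(rn$majority)

  # all-empty profiles are undetermined
  away <- list(chrom = "chr1", start = 5e5, end = 5e5 + 100)
  ru <- register_consistency(away, libs, 21)
  expect_true(ru$undetermined)
})
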