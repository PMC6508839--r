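# Shared mini-scene: a few true phased loci and noise loci in 3 libraries.
mini_screen_fixture <- function(n_phas = 6, n_noise = 3, n_lib = 3, seed = 9) {
  set.seed(seed)
  s <- 21
  spacing <- 400
  loci <- data.frame(
    locus_id = sprintf("L%02d", seq_len(n_phas + n_noise)),
    chrom = "chr1",
    start = spacing * (seq_len(n_phas + n_noise) - 1),
    end = spacing * (seq_len(n_phas + n_noise) - 1) + 250
  )
  libs <- lapply(seq_len(n_lib), function(j) {
    parts <- lapply(seq_len(n_phas + n_noise), function(i) {
      base <- loci$start[i] + 10
      if (i <= n_phas) {
        pos <- base + s * (0:9)
        data.frame(chrom = "chr1", start = c(pos, pos - 2),
                   length = s, strand = rep(c("+", "-"), each = 10),
                   count = rpois(20, 4) + 1, n_placements = 1)
      } else {
        data.frame(chrom = "chr1",
                   start = base + sample(0:220, 30, TRUE), length = s,
                   strand = sample(c("+", "-"), 30, TRUE), count = 1,
                   n_placements = 1)
      }
    })
    srna_library(do.call(rbind, parts), paste0("lib", j),
                 total_primary = 1e6)
  })
  list(loci = loci, libs = libs, s = s, n_phas = n_phas)
}

test_that("cutoff calibration reproduces hand-computed quantiles", {
  mk <- function(lo, p, ra) data.frame(
    locus_id = sprintf("c%02d", seq_along(lo)), library_id = "lib1",
    score_logodds = lo, pval_hypergeom = p, score_ratio = ra)

  # degenerate distribution: all controls score exactly 30
  cd <- calibrate_cutoffs(mk(rep(30, 10), rep(1e-9, 10), rep(5, 10)))
  expect_equal(cd$cutoff_logodds, 30)
  expect_equal(cd$cutoff_ratio, 5)

  # {10, 20, ..., 100} at quantile 0.05 under the documented type-6 rule:
  # h = 11 * 0.05 = 0.55 < 1 clamps to the smallest order statistic
  cq <- calibrate_cutoffs(mk(seq(10, 100, 10), rep(1e-9, 10), seq(10, 100, 10)))
  expect_equal(cq$cutoff_logodds, 10)

  # p cutoff is the (1 - q) percentile capped at 0.05
  cp <- calibrate_cutoffs(mk(rep(30, 10), rep(0.2, 10), rep(5, 10)))
  expect_equal(cp$cutoff_pval, 0.05)

  expect_error(calibrate_cutoffs(NULL), "explicit cutoffs")
  expect_error(calibrate_cutoffs(mk(1:3, rep(.1, 3), 1:3)), ">= 5")
})

test_that("per-locus calibration uses each control's weakest library", {
  res <- data.frame(
    locus_id = rep(c("a", "b", "c"), each = 2),
    library_id = rep(c("l1", "l2"), 3),
    score_logodds = c(10, 40, 50, 60, 70, 90),
    pval_hypergeom = c(1e-3, 1e-9, 1e-8, 1e-7, 1e-6, 1e-12),
    score_ratio = c(2, 8, 9, 9, 7, 7))
  cc <- calibrate_cutoffs(res, quantile = 0.5)
  # per-locus minima are {10, 50, 70}; type-6 median is the 2nd order stat
  expect_equal(cc$cutoff_logodds, 50)
  # per-locus maxima of p are {1e-3, 1e-7, 1e-6}; median = 1e-6
  expect_equal(cc$cutoff_pval, 1e-6)
  cc2 <- calibrate_cutoffs(res, quantile = 0.5, per_locus = FALSE)
  expect_false(isTRUE(all.equal(cc$cutoff_logodds, cc2$cutoff_logodds)))
})

test_that("the consensus screen requires every cell and tallies the Venn", {
  fx <- mini_screen_fixture()
  pt <- phase_table(fx$loci[seq_len(fx$n_phas), ], fx$libs, fx$s)
  cuts <- calibrate_cutoffs(pt, quantile = 0.05)
  rep <- screen_loci(fx$loci, fx$libs, fx$s, cuts)

  expect_true(any(rep$consensus[seq_len(fx$n_phas)]))
  expect_false(any(rep$consensus[-seq_len(fx$n_phas)]))
  # consensus iff all 3 x L cells pass
  for (i in seq_len(nrow(fx$loci))) {
    expect_identical(unname(rep$consensus[i]), all(rep$pass[i, , ]))
  }
  # Venn cells sum to loci passing >= 1 detector in all libraries
  expect_equal(sum(rep$venn),
               sum(apply(rep$all_lib_pass, 1, any)))
})

test_that("tightening any cutoff never enlarges the consensus set", {
  fx <- mini_screen_fixture()
  pt <- phase_table(fx$loci[seq_len(fx$n_phas), ], fx$libs, fx$s)
  cuts <- calibrate_cutoffs(pt, quantile = 0.05)
  base <- screen_loci(fx$loci, fx$libs, fx$s, cuts)
  tighter <- list(
    phas_cutoffs(cuts$cutoff_logodds * 2, cuts$cutoff_pval, cuts$cutoff_ratio),
    phas_cutoffs(cuts$cutoff_logodds, cuts$cutoff_pval / 10, cuts$cutoff_ratio),
    phas_cutoffs(cuts$cutoff_logodds, cuts$cutoff_pval, cuts$cutoff_ratio + 1)
  )
  for (ct in tighter) {
    rt <- screen_loci(fx$loci, fx$libs, fx$s, ct)
    expect_true(all(rep(base$consensus, 1)[rt$consensus]))
    expect_lte(sum(rt$consensus), sum(base$consensus))
  }
})

test_that("a locus with no reads in one library fails consensus there", {
  fx <- mini_screen_fixture(n_phas = 2, n_noise = 0)
  # drop locus 1's reads from library 2 entirely
  libs <- fx$libs
  r <- libs[[2]]$reads
  keep <- !(r$start < fx$loci$end[1] & r$start + r$length > fx$loci$start[1])
  libs[[2]] <- srna_library(r[keep, ], "lib2", total_primary = 1e6)
  pt <- phase_table(fx$loci, fx$libs, fx$s)
  cuts <- calibrate_cutoffs(pt, quantile = 0.05)
  rep <- screen_loci(fx$loci, libs, fx$s, cuts)
  expect_false(rep$consensus[1])
  expect_true(rep$results$no_data[rep$results$locus_id == "L01" &
                                  rep$results$library_id == "lib2"])
  # passing in L - 1 libraries is not consensus
  expect_true(all(rep$pass["L01", -2, ]))
})

test_that("diagnostics support true phased loci and reject register-less ones", {
  fx <- mini_screen_fixture()
  pt <- phase_table(fx$loci[seq_len(fx$n_phas), ], fx$libs, fx$s)
  cuts <- calibrate_cutoffs(pt, quantile = 0.05)
  rep <- screen_loci(fx$loci, fx$libs, fx$s, cuts)
  dg <- diagnose_screen(rep, fx$libs, which = seq_len(nrow(fx$loci)))
  expect_equal(dg$verdict[seq_len(fx$n_phas)],
               rep("PHAS-supported", fx$n_phas))
  expect_true(all(dg$verdict[-seq_len(fx$n_phas)] == "not-PHAS-supported"))
  # majority criterion fails whenever the dominant fraction is below 0.5
  expect_true(all(dg$min_dominant_fraction[dg$majority_all_libraries] > 0.5))
  expect_true(all(dg$min_dominant_fraction[!dg$majority_all_libraries] <= 0.5))
})
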