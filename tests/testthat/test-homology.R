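QUERY22 <- "TTTGGATTGAAGGGAGCTCTTC"  # 22-nt query, DNA alphabet

test_that("genome scan finds planted variants up to the mismatch budget", {
  set.seed(31)
  g <- random_dna(10000)
  plant <- function(seq, at, k) {
    ch <- strsplit(seq, "")[[1]]
    if (k > 0) {
      pos <- sample(length(ch), k)
      for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    }
    substr(g, at + 1, at + nchar(seq)) <<- paste(ch, collapse = "")
    at
  }
  p0 <- plant(QUERY22, 1000, 0)
  p2 <- plant(QUERY22, 3000, 2)
  p3 <- plant(QUERY22, 5000, 3)
  hits <- scan_homologs(c(chrA = g), QUERY22, max_mm = 2)
  expect_true(any(hits$start == p0 & hits$n_mismatches == 0))
  expect_true(any(hits$start == p2 & hits$n_mismatches == 2))
  expect_false(any(hits$start == p3))

  # exact agreement with the position-by-position oracle
  oracle <- brute_scan_homologs(g, QUERY22, 2)
  expect_equal(hits[, c("start", "strand", "n_mismatches")], oracle,
               ignore_attr = TRUE)
})

test_that("scan rejects ambiguous queries and never matches genome Ns", {
  expect_error(scan_homologs(c(c1 = "ACGTACGT"), "ACGNACGTACGTACGTAC"),
               "ambiguous")
  g <- paste0(strrep("A", 50), chartr("T", "N", QUERY22), strrep("A", 50))
  hits <- scan_homologs(c(c1 = g), QUERY22, max_mm = 2)
  expect_false(any(hits$n_mismatches <= 2 & hits$start == 50 &
                   grepl("N", hits$matched_sequence)))
})

test_that("context extraction flanks, truncates and strand-flips correctly", {
  set.seed(32)
  g <- c(ctg = random_dna(10000))
  hit <- data.frame(chrom = "ctg", start = 500, end = 521, strand = "+")
  cx <- extract_context(hit, g, flank = 200)
  expect_equal(nchar(cx$context), 421)
  expect_equal(c(cx$mature_start, cx$mature_end), c(200, 221))
  expect_false(cx$truncated_left || cx$truncated_right)

  edge <- data.frame(chrom = "ctg", start = 50, end = 71, strand = "+")
  ce <- extract_context(edge, g, flank = 200)
  expect_equal(nchar(ce$context), 271)
  expect_true(ce$truncated_left)

  minus <- data.frame(chrom = "ctg", start = 500, end = 521, strand = "-")
  cm <- extract_context(minus, g, flank = 200)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cx$context)))
  expect_equal(cm$context, rc)
  expect_equal(substr(cm$context, cm$mature_start + 1, cm$mature_end),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(
                   substr(cx$context, cx$mature_start + 1, cx$mature_end)))))
})

test_that("hairpin check accepts inverted repeats and rejects weak duplexes", {
  set.seed(33)
  mature <- QUERY22
  star <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mature)))
  ctx <- paste0(random_dna(40), star, "AAACAAAC", mature, random_dna(40))
  ms <- 40 + 22 + 8
  hp <- hairpin_check(ctx, ms, ms + 22)
  expect_equal(hp$verdict, "plausible")
  expect_equal(hp$unpaired, 0)
  # reported star window is the planted inverted repeat
  expect_equal(c(hp$star_start, hp$star_end), c(40, 62))

  # 6 unpaired mature positions exceed the threshold; substituting the
  # mature base itself at the paired star position forbids both the
  # Watson-Crick pair and the wobble
  star6 <- strsplit(star, "")[[1]]
  mvec <- strsplit(mature, "")[[1]]
  for (k in c(3, 6, 9, 12, 15, 18)) star6[k] <- mvec[23 - k]
  ctx6 <- paste0(random_dna(40), paste(star6, collapse = ""), "AAACAAAC",
                 mature, random_dna(40))
  hp6 <- hairpin_check(ctx6, ms, ms + 22)
  expect_equal(hp6$verdict, "implausible")
  expect_gte(hp6$unpaired, 6)

  # short context
  expect_equal(hairpin_check("ACGTACGT", 0, 4)$verdict, "implausible")
})

test_that("an external folder hook overrides the internal duplex search", {
  mature <- QUERY22
  star <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mature)))
  ctx <- paste0(star, "AAACAAAC", mature)
  ms <- 22 + 8
  # pretend-folder pairing the two arms perfectly
  folder <- function(seq) {
    paste0(strrep("(", 22), strrep(".", 8), strrep(")", 22),
           strrep(".", nchar(seq) - 52))
  }
  long_ctx <- paste0(ctx, strrep("A", 30))
  hp <- hairpin_check(long_ctx, ms, ms + 22, folder = folder)
  expect_equal(hp$verdict, "plausible")
  # a folder reporting everything unpaired forces implausible
  none <- function(seq) strrep(".", nchar(seq))
  expect_equal(hairpin_check(long_ctx, ms, ms + 22, folder = none)$verdict,
               "implausible")
})

test_that("collapsed-read queries honor mismatch and length tolerances", {
  reads <- data.frame(
    sequence = c(QUERY22,                                   # exact
                 sub("TTT", "AAA", QUERY22),                # 3 mismatches
                 substr(QUERY22, 2, 21)),                   # 20-nt sub-read
    count = c(7, 3, 2))
  q <- query_collapsed_reads(reads, QUERY22, max_mm = 2)
  expect_true(q$present)
  expect_equal(q$total_abundance, 9)  # exact + end-gap-free sub-read
  expect_equal(brute_query_collapsed(reads$sequence, QUERY22, 2, 2),
               c(TRUE, FALSE, TRUE))

  only3 <- query_collapsed_reads(reads[2, ], QUERY22, max_mm = 2)
  expect_false(only3$present)
  empty <- query_collapsed_reads(reads[0, ], QUERY22)
  expect_false(empty$present)
  expect_equal(empty$total_abundance, 0)
})

test_that("Allen scoring matches the position-weighted scheme by hand", {
  revcomp <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  sr <- "TGACCTGGGACTGAAGGGAGC"
  site <- revcomp(sr)
  expect_equal(allen_score(sr, site)$score, 0)

  # G:U wobble at small RNA position 5 (core): 0.5 doubled = 1.0
  # small RNA pos 5 pairs site position L - 4; make site base T where sr has G
  sr5 <- sr
  substr(sr5, 5, 5) <- "G"
  site5 <- revcomp(sr5)
  substr(site5, 21 - 4, 21 - 4) <- "T"
  expect_equal(allen_score(sr5, site5)$score, 1.0)

  # a plain mismatch at position 20 (outside the core) costs 1.0
  site20 <- revcomp(sr)
  pos_in_site <- 21 - 20 + 1
  old <- substr(site20, pos_in_site, pos_in_site)
  substr(site20, pos_in_site, pos_in_site) <-
    setdiff(c("A", "C", "G", "T"),
            c(old, chartr("ACGT", "TGCA", substr(sr, 20, 20)),
              if (substr(sr, 20, 20) %in% c("G", "T")) "T" else character(0)))[1]
  sc <- allen_score(sr, site20)
  expect_equal(sc$score, 1.0)
  expect_equal(sum(sc$penalties != 0), 1)

  expect_error(allen_score("ACGT", "ACGTA"), "equal length")
})

test_that("Allen pair states are symmetric under strand role swap", {
  # Swapping which strand is called 'small RNA' mirrors the duplex: the
  # undoubled per-position penalties must be reversed, pair-for-pair
  # (the doubled totals differ because the 5' core moves with the strand).
  set.seed(34)
  for (i in 1:10) {
    sr <- random_dna(21)
    site <- random_dna(21)
    a <- allen_score(sr, site)
    b <- allen_score(site, sr)
    undouble <- function(x) {
      core <- seq_along(x$penalties) >= 2 & seq_along(x$penalties) <= 13
      x$penalties / ifelse(core, 2, 1)
    }
    expect_equal(undouble(a), rev(undouble(b)))
  }
})

test_that("target prediction applies the cutoff rule and nests in it", {
  revcomp <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  mir <- "TGACCTGGGACTGAAGGGAGC"
  target <- paste0(random_dna(50), revcomp(mir), random_dna(50))
  hits <- predict_targets(c(miR1 = mir), c(t1 = target), cutoff = 3)
  expect_true(any(hits$score == 0))
  expect_equal(hits$target_start[hits$score == 0], 50)

  # nesting: hit sets grow monotonically with the cutoff
  set.seed(35)
  t2 <- random_dna(300)
  h_inf <- predict_targets(c(miR1 = mir), c(t2 = t2), cutoff = Inf)
  expect_equal(nrow(h_inf), 300 - 21 + 1)
  prev <- -1
  for (cut in c(0, 3, 6, 10)) {
    n <- nrow(predict_targets(c(miR1 = mir), c(t2 = t2), cutoff = cut))
    expect_gte(n, prev)
    prev <- n
  }
  # boundary: score exactly 3.0 reported, 3.5 not
  h3 <- predict_targets(c(miR1 = mir), c(t2 = t2), cutoff = 3)
  expect_true(all(h3$score <= 3))
})
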