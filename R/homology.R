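# Mature-miRNA homolog scanning, hairpin-context plausibility, collapsed
# read querying, and Allen-score target prediction.

norm_dna <- function(x) {
  x <- toupper(gsub("\\s", "", x))
  chartr("U", "T", x)
}

as_dnastringset <- function(genome) {
  if (is(genome, "DNAStringSet")) return(genome)
  if (is(genome, "DNAString")) return(Biostrings::DNAStringSet(genome))
  if (is.character(genome)) {
    if (length(genome) == 1L && file.exists(genome)) {
      return(Biostrings::readDNAStringSet(genome))
    }
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(Biostrings::DNAStringSet(norm_dna(genome)))
  }
  stop("genome must be a DNAStringSet, named character vector, or FASTA path")
}

#' Scan a genome for mature-miRNA homologs
#'
#' Reports every genomic window on either strand whose Hamming distance to
#' the query is at most `max_mm` substitutions (no indels, matching an
#' aligner run with a mismatch allowance). U/T equivalence is applied to the
#' query; ambiguous genome bases never match.
#'
#' @param genome `DNAStringSet`, named character vector of sequences, or
#'   FASTA path.
#' @param query mature miRNA sequence (18-26 nt, RNA or DNA alphabet, no
#'   ambiguity codes).
#' @param max_mm maximum mismatches (default 2).
#' @return data.frame of hits sorted by (chrom, start): chrom, start, end
#'   (0-based half-open), strand, n_mismatches, matched_sequence (genomic
#'   plus-strand sequence of the window).
#' @export
scan_homologs <- function(genome, query, max_mm = 2) {
  genome <- as_dnastringset(genome)
  query <- norm_dna(query)
  if (nchar(query) < 18 || nchar(query) > 26) {
    stop("query length must be 18-26 nt")
  }
  if (grepl("[^ACGT]", query)) stop("ambiguous bases in query are not allowed")
  q <- Biostrings::DNAString(query)
  qrc <- Biostrings::reverseComplement(q)
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") q else qrc
      mt <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm,
                                     fixed = TRUE)
      if (!length(mt)) next
      seqs <- as.character(mt)
      ref <- as.character(if (strand == "+") q else qrc)
      mm <- vapply(seqs, function(sq) {
        sum(strsplit(sq, "")[[1]] != strsplit(ref, "")[[1]])
      }, integer(1), USE.NAMES = FALSE)
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = chrom,
        start = Biostrings::start(mt) - 1L,
        end = Biostrings::end(mt),
        strand = strand,
        n_mismatches = mm,
        matched_sequence = seqs,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), n_mismatches = integer(),
                      matched_sequence = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[out$n_mismatches <= max_mm, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the genomic context around a homolog hit
#'
#' Returns the hit plus `flank` nt on each side, truncated at contig edges
#' (with the truncation flagged). Minus-strand hits are reverse-complemented
#' so that the mature sequence reads 5'->3' within the context.
#'
#' @param hit one-row data.frame from [scan_homologs()].
#' @param genome same genome the scan used.
#' @param flank nt of context on each side (default 200).
#' @return list with `context` (character), `mature_start`, `mature_end`
#'   (0-based half-open span of the mature sequence within the context),
#'   `truncated_left`, `truncated_right`.
#' @export
extract_context <- function(hit, genome, flank = 200) {
  genome <- as_dnastringset(genome)
  if (is.data.frame(hit)) {
    stopifnot(nrow(hit) == 1L)
    hit <- as.list(hit)
  }
  subj <- genome[[hit$chrom]]
  clen <- length(subj)
  lo <- max(0L, hit$start - flank)
  hi <- min(clen, hit$end + flank)
  ctx <- as.character(Biostrings::subseq(subj, lo + 1L, hi))
  trunc_l <- lo > hit$start - flank
  trunc_r <- hi < hit$end + flank
  m_start <- hit$start - lo
  m_end <- hit$end - lo
  if (identical(hit$strand, "-")) {
    ctx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ctx)))
    n <- nchar(ctx)
    new_start <- n - m_end
    m_end <- n - m_start
    m_start <- new_start
    tmp <- trunc_l; trunc_l <- trunc_r; trunc_r <- tmp
  }
  list(context = ctx, mature_start = m_start, mature_end = m_end,
       truncated_left = trunc_l, truncated_right = trunc_r)
}

base_pairs <- function(a, b) {
  # Watson-Crick or G:T(U) wobble, DNA alphabet.
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Hairpin plausibility of a homolog context
#'
#' Tests whether the mature span can form a miRNA/miRNA* duplex on a single
#' stem: the best gap-free antiparallel pairing of the mature sequence
#' against any non-overlapping window of the context (leaving a loop of at
#' least `min_loop` nt) is found, and the verdict is `plausible` when the
#' mature sequence has at most `max_unpaired` unpaired positions and no run
#' of more than `max_consecutive_unpaired` unpaired positions in that
#' duplex. An optional `folder` function delegates the structure to an
#' external thermodynamic folder (see [rnafold_folder()]).
#'
#' @param context context sequence (character).
#' @param mature_start,mature_end 0-based half-open span of the mature
#'   sequence within the context.
#' @param max_unpaired maximum unpaired mature positions (default 5).
#' @param max_consecutive_unpaired maximum run of unpaired mature positions
#'   (default 3).
#' @param min_loop minimum loop length between the duplex arms (default 3).
#' @param folder optional function(sequence) returning a dot-bracket
#'   structure string; when supplied, pairing of the mature span is read
#'   from that structure instead of the internal duplex search.
#' @return list with `verdict` ("plausible"/"implausible"), `reason`,
#'   `unpaired`, `max_run`, `star_start`, `star_end` (0-based half-open span
#'   of the best miRNA* window; NA under an external folder).
#' @export
hairpin_check <- function(context, mature_start, mature_end,
                          max_unpaired = 5, max_consecutive_unpaired = 3,
                          min_loop = 3, folder = NULL) {
  context <- norm_dna(context)
  n <- nchar(context)
  L <- mature_end - mature_start
  stopifnot(mature_start >= 0, mature_end <= n, L >= 1)
  if (n < 60) {
    return(list(verdict = "implausible", reason = "context shorter than 60 nt",
                unpaired = NA_integer_, max_run = NA_integer_,
                star_start = NA_integer_, star_end = NA_integer_))
  }
  ch <- strsplit(context, "")[[1]]
  mature <- ch[(mature_start + 1):mature_end]
  if (!is.null(folder)) {
    db <- folder(context)
    paired <- pairing_from_dotbracket(db)
    # a mature position counts as paired only when its partner lies outside
    # the mature span (a genuine miRNA* arm)
    partners <- paired[(mature_start + 1):mature_end]
    outside <- !is.na(partners) &
      (partners <= mature_start | partners > mature_end)
    unp <- !outside
    runs <- rle(unp)
    max_run <- if (any(unp)) max(runs$lengths[runs$values]) else 0L
    ok <- sum(unp) <= max_unpaired && max_run <= max_consecutive_unpaired
    return(list(verdict = if (ok) "plausible" else "implausible",
                reason = if (ok) "external fold duplex criteria met"
                         else "external fold duplex criteria failed",
                unpaired = sum(unp), max_run = max_run,
                star_start = NA_integer_, star_end = NA_integer_))
  }
  # Gap-free duplex search: mature position t (0-based within mature) pairs
  # context position j0 - t for a candidate 3' pairing anchor j0. The star
  # window [j0 - L + 1, j0] must not invade the mature span or the loop.
  best <- list(unpaired = L + 1L, max_run = L + 1L, j0 = NA_integer_)
  for (side in c("down", "up")) {
    j0s <- if (side == "down") {
      seq.int(mature_end + min_loop + L - 1L, n - 1L)
    } else {
      if (mature_start - min_loop - 1L < L - 1L) integer(0)
      else seq.int(L - 1L, mature_start - min_loop - 1L)
    }
    if (!length(j0s)) next
    for (j0 in j0s) {
      partner <- ch[j0 + 1L - (seq_len(L) - 1L)]
      unp <- !base_pairs(mature, partner)
      n_unp <- sum(unp)
      if (n_unp < best$unpaired) {
        runs <- rle(unp)
        best <- list(unpaired = n_unp,
                     max_run = if (n_unp) max(runs$lengths[runs$values]) else 0L,
                     j0 = j0)
      }
    }
  }
  if (is.na(best$j0)) {
    return(list(verdict = "implausible", reason = "no candidate star window",
                unpaired = NA_integer_, max_run = NA_integer_,
                star_start = NA_integer_, star_end = NA_integer_))
  }
  ok <- best$unpaired <= max_unpaired && best$max_run <= max_consecutive_unpaired
  list(verdict = if (ok) "plausible" else "implausible",
       reason = if (ok) "duplex criteria met" else
         sprintf("%d unpaired mature positions (max run %d)",
                 best$unpaired, best$max_run),
       unpaired = best$unpaired, max_run = best$max_run,
       star_start = best$j0 - L + 1L,
       star_end = best$j0 + 1L)
}

# Partner index (1-based) per position from a dot-bracket string; NA when
# unpaired.
pairing_from_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  out <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      out[i] <- j
      out[j] <- i
    }
  }
  out
}

#' RNAfold-backed folder hook
#'
#' Returns a function suitable for `hairpin_check(folder = ...)` that runs
#' the ViennaRNA `RNAfold` executable and returns the minimum-free-energy
#' dot-bracket structure.
#'
#' @param exe path to the RNAfold executable.
#' @return function(sequence) -> dot-bracket string.
#' @export
rnafold_folder <- function(exe = "RNAfold") {
  if (Sys.which(exe) == "") stop("RNAfold executable not found on PATH")
  function(sequence) {
    out <- system2(exe, args = c("--noPS"), input = norm_dna(sequence),
                   stdout = TRUE)
    sub("^([().]+).*$", "\\1", out[2])
  }
}

#' Query a collapsed (non-redundant) read set for a sequence
#'
#' End-gap-free comparison tolerating a length difference of up to
#' `len_tol` nt: the shorter sequence is slid along the longer and the
#' minimum Hamming distance over offsets is taken.
#'
#' @param reads data.frame with columns `sequence` and `count` (collapsed
#'   non-redundant reads), or a character vector of sequences.
#' @param query sequence to look for (U/T equivalent).
#' @param max_mm maximum mismatches (default 2).
#' @param len_tol maximum length difference (default 2).
#' @return list with `hits` (matching rows plus `n_mismatches`),
#'   `total_abundance` (summed counts of hits), `present` (any hit).
#' @export
query_collapsed_reads <- function(reads, query, max_mm = 2, len_tol = 2) {
  if (is.character(reads)) reads <- data.frame(sequence = reads, count = 1)
  stopifnot(all(c("sequence", "count") %in% names(reads)))
  query <- norm_dna(query)
  seqs <- norm_dna(reads$sequence)
  mm <- vapply(seqs, function(sq) {
    if (abs(nchar(sq) - nchar(query)) > len_tol) return(NA_integer_)
    a <- if (nchar(sq) <= nchar(query)) sq else query
    b <- if (nchar(sq) <= nchar(query)) query else sq
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    la <- length(av); lb <- length(bv)
    min(vapply(0:(lb - la), function(off) {
      sum(av != bv[(off + 1):(off + la)])
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
  keep <- !is.na(mm) & mm <= max_mm
  hits <- reads[keep, , drop = FALSE]
  hits$n_mismatches <- mm[keep]
  rownames(hits) <- NULL
  list(hits = hits, total_abundance = sum(hits$count), present = any(keep))
}

#' Allen-style target alignment score
#'
#' Gap-free antiparallel comparison of a small RNA (5'->3') against a target
#' site (5'->3'): small RNA position i pairs site position L - i + 1. Each
#' Watson-Crick pair scores 0, each G:U wobble 0.5, any other mismatch 1;
#' penalties at small RNA positions 2-13 (the 5' core) are doubled.
#'
#' @param small_rna small RNA sequence, 5'->3'.
#' @param site target site sequence, 5'->3', same length.
#' @return list with `score`, `penalties` (per small RNA position), and the
#'   normalized sequences.
#' @export
allen_score <- function(small_rna, site) {
  small_rna <- norm_dna(small_rna)
  site <- norm_dna(site)
  L <- nchar(small_rna)
  if (nchar(site) != L) {
    stop("small RNA and site must be equal length under the gap-free model")
  }
  sr <- strsplit(small_rna, "")[[1]]
  st <- rev(strsplit(site, "")[[1]])   # antiparallel: position i vs L - i + 1
  wc <- (sr == "A" & st == "T") | (sr == "T" & st == "A") |
    (sr == "G" & st == "C") | (sr == "C" & st == "G")
  wobble <- (sr == "G" & st == "T") | (sr == "T" & st == "G")
  pen <- ifelse(wc, 0, ifelse(wobble, 0.5, 1))
  core <- seq_len(L) >= 2 & seq_len(L) <= 13
  pen[core] <- pen[core] * 2
  list(score = sum(pen), penalties = pen, small_rna = small_rna, site = site)
}

#' Predict small RNA targets by Allen score
#'
#' Scores every window of each target sequence against each small RNA and
#' reports alignments at or below the cutoff (default 3, the conventional
#' plant-miRNA targeting threshold).
#'
#' @param mirnas named character vector of small RNA sequences (5'->3').
#' @param targets named character vector of target sequences.
#' @param cutoff maximum Allen score (default 3; `Inf` returns every window).
#' @return data.frame sorted by score: mirna, target, target_start,
#'   target_end (0-based half-open window), site, score, best_for_target
#'   (flag on each target's best hit).
#' @export
predict_targets <- function(mirnas, targets, cutoff = 3) {
  if (is.null(names(mirnas))) names(mirnas) <- paste0("miR", seq_along(mirnas))
  if (is.null(names(targets))) names(targets) <- paste0("t", seq_along(targets))
  rows <- list()
  for (mn in names(mirnas)) {
    mseq <- norm_dna(mirnas[[mn]])
    L <- nchar(mseq)
    for (tn in names(targets)) {
      tseq <- norm_dna(targets[[tn]])
      if (nchar(tseq) < L) next
      for (ws in 0:(nchar(tseq) - L)) {
        site <- substr(tseq, ws + 1, ws + L)
        sc <- allen_score(mseq, site)$score
        if (sc <= cutoff) {
          rows[[length(rows) + 1L]] <- data.frame(
            mirna = mn, target = tn, target_start = ws, target_end = ws + L,
            site = site, score = sc, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(), target = character(),
                      target_start = integer(), target_end = integer(),
                      site = character(), score = numeric(),
                      best_for_target = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$mirna, out$target, out$target_start), ,
             drop = FALSE]
  out$best_for_target <- !duplicated(out$target)
  rownames(out) <- NULL
  out
}
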