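# The phase-register machinery and the three phasing statistics.
#
# A read's phase register is the residue class (mod s) of its 5' end in the
# phase frame. Minus-strand reads are shifted so that the two strands of a
# perfect duplex with 2-nt 3' overhangs share one register: for a plus read
# the register is start mod s; for a minus read it is (end + 2) mod s, where
# end is the 0-based half-open right edge. Equivalently every read maps to a
# strand-collapsed "phase coordinate" start (for +) or end + 2 - s (for -);
# duplex partners share the same coordinate exactly, and register =
# coordinate mod s.

#' Phase register of aligned reads
#'
#' @param start 0-based leftmost aligned position(s).
#' @param length read length(s) in nt.
#' @param strand "+" or "-" (vectorized).
#' @param s phase size in nt (21 or 24).
#' @return integer register indices in 0..s-1.
#' @export
register_of <- function(start, length, strand, s) {
  stopifnot(s >= 2)
  ifelse(strand == "+", start %% s, (start + length + 2) %% s)
}

#' Strand-collapsed phase coordinate of aligned reads
#'
#' Plus reads map to their 5' position; minus reads to `end + 2 - s`, so a
#' perfect 2-nt-3'-overhang duplex partner of a plus read at position p also
#' maps to p. `register_of()` equals this coordinate mod s.
#'
#' @inheritParams register_of
#' @return integer genomic phase coordinates.
#' @export
phase_coordinate <- function(start, length, strand, s) {
  ifelse(strand == "+", start, start + length + 2 - s)
}

# Reads of a library eligible for an s-nt phasing analysis of one locus:
# footprint overlaps the locus and length within s +/- tolerance.
eligible_reads <- function(lib, locus, s, length_tolerance = 0) {
  r <- reads_in_locus(lib, locus$chrom, locus$start, locus$end)
  r[abs(r$length - s) <= length_tolerance, , drop = FALSE]
}

as_locus <- function(locus) {
  if (is.data.frame(locus)) {
    stopifnot(nrow(locus) == 1L)
    locus <- as.list(locus)
  }
  stopifnot(!is.null(locus$chrom), !is.null(locus$start), !is.null(locus$end))
  locus
}

#' Abundance-weighted phase-register profile of a locus
#'
#' @param lib an `srna_library`.
#' @param locus one-row locus data.frame or list with chrom, start, end.
#' @param s phase size in nt.
#' @param length_tolerance include reads of length within `s +/- tolerance`
#'   (default 0: exact-length reads only).
#' @return list with `phase_size`, `register_abundance` (length s),
#'   `total`, `dominant_register`, `dominant_fraction`, and `tied` (TRUE
#'   when the argmax was not unique; ties break toward the smallest index).
#' @export
register_profile <- function(lib, locus, s, length_tolerance = 0) {
  locus <- as_locus(locus)
  r <- eligible_reads(lib, locus, s, length_tolerance)
  ab <- numeric(s)
  if (nrow(r)) {
    reg <- register_of(r$start, r$length, r$strand, s)
    tab <- rowsum(r$count, reg)
    ab[as.integer(rownames(tab)) + 1L] <- tab[, 1]
  }
  tot <- sum(ab)
  if (tot == 0) {
    return(list(phase_size = s, register_abundance = ab, total = 0,
                dominant_register = NA_integer_, dominant_fraction = 0,
                tied = FALSE))
  }
  best <- which(ab == max(ab))
  list(phase_size = s, register_abundance = ab, total = tot,
       dominant_register = min(best) - 1L,
       dominant_fraction = max(ab) / tot,
       tied = length(best) > 1L)
}

#' Log-odds phasing score kernel
#'
#' `ln[(1 + 10 * P / (1 + U))^(k - 2)]` for k >= 3, else 0, where P is the
#' in-phase abundance, U the out-of-phase abundance and k the number of
#' occupied phase positions in the window.
#'
#' @param P in-phase abundance (>= 0).
#' @param U out-of-phase abundance (>= 0).
#' @param k occupied phase positions (integer >= 0).
#' @return numeric score(s) >= 0.
#' @export
phase_logodds_score <- function(P, U, k) {
  ifelse(k >= 3, (k - 2) * log1p(10 * P / (1 + U)), 0)
}

#' Hypergeometric upper tail P(X >= x)
#'
#' Probability of observing at least `x` occupied in-register positions when
#' `n` of `N` positions are occupied uniformly at random and `K` of the N
#' are in-register.
#'
#' @param x observed in-register occupied positions.
#' @param N total positions.
#' @param K in-register positions.
#' @param n occupied positions.
#' @return upper-tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(x, N, K, n) {
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

# Shared windowed scan over one locus in one library.
#
# Builds the (register x cycle) abundance and occupancy grids on the
# strand-collapsed phase coordinates, then evaluates every window of m
# cycles (stepping one cycle, anchored at the locus start so all three
# statistics are invariant under translation by multiples of s) against
# every candidate register. Loci shorter than m cycles are evaluated as a
# single full-span window.
phase_scan <- function(lib, locus, s, m, length_tolerance = 0,
                       drift_weight = 0.5) {
  locus <- as_locus(locus)
  r <- eligible_reads(lib, locus, s, length_tolerance)
  empty <- list(n_reads = 0L, abundance = 0,
                logodds = 0, logodds_register = NA_integer_,
                logodds_window = c(NA_real_, NA_real_),
                pval = 1, pval_register = NA_integer_,
                pval_window = c(NA_real_, NA_real_),
                ratio = 0, ratio_register = NA_integer_,
                ratio_window = c(NA_real_, NA_real_))
  if (!nrow(r)) return(empty)
  coord <- phase_coordinate(r$start, r$length, r$strand, s)
  # Origin congruent to locus start mod s, at or left of every coordinate.
  origin <- locus$start - s * ceiling(max(0, locus$start - min(coord)) / s)
  rel <- coord - origin
  ci <- rel %/% s
  reg <- rel %% s
  C <- max(ci) + 1L
  m_eff <- min(m, C)
  slot <- ci * s + reg + 1L
  A <- numeric(C * s)
  tabA <- rowsum(r$count, slot)
  A[as.integer(rownames(tabA))] <- tabA[, 1]
  M <- matrix(A, nrow = s)              # M[register + 1, cycle + 1]
  Occ <- matrix(as.numeric(A > 0), nrow = s)
  row_cumsum <- function(mat) {
    if (ncol(mat) > 1L) t(apply(mat, 1, cumsum)) else mat
  }
  csA <- cbind(0, row_cumsum(M))             # s x (C + 1)
  csO <- cbind(0, row_cumsum(Occ))
  W <- C - m_eff + 1L                        # number of windows
  lo <- seq_len(W)
  hi <- lo + m_eff
  P <- csA[, hi, drop = FALSE] - csA[, lo, drop = FALSE]   # s x W abundance
  X <- csO[, hi, drop = FALSE] - csO[, lo, drop = FALSE]   # s x W occupancy
  tot <- colSums(P)
  n_occ <- colSums(X)

  win_iv <- function(j) c(origin + (j - 1) * s, origin + (j - 1 + m_eff) * s)
  argmax2 <- function(S) {
    # (register, window) of the maximum; ties -> smallest register index,
    # then earliest window.
    j <- which.max(apply(S, 2, max))
    i <- which.max(S[, j])
    c(i, j)
  }

  # Algorithm B: hypergeometric p-value; within a window (N, K, n fixed) the
  # tail is decreasing in x, so the per-window minimum is at the register
  # with the most occupied in-register positions.
  N <- m_eff * s
  K <- m_eff
  xmax <- apply(X, 2, max)
  pw <- hypergeom_tail(xmax, N, K, n_occ)
  pw[n_occ == 0] <- 1
  jB <- which.min(pw)
  rB <- which.max(X[, jB]) - 1L

  # Algorithm A: log-odds with +/-1 nt drift tolerance at discounted weight.
  up <- c(2:s, 1)
  dn <- c(s, 1:(s - 1))
  Pd <- P + drift_weight * (P[up, , drop = FALSE] + P[dn, , drop = FALSE])
  Ud <- matrix(rep(tot, each = s), nrow = s) - P - P[up, , drop = FALSE] -
    P[dn, , drop = FALSE]
  kA <- X + X[up, , drop = FALSE] + X[dn, , drop = FALSE]
  SA <- phase_logodds_score(Pd, Ud, kA)
  ia <- argmax2(SA)

  # Algorithm C: phased-fraction ratio times occupied positions, exact
  # registers, no drift tolerance.
  denom <- ifelse(tot > 0, tot, 1)
  SC <- sweep(P, 2, denom, "/") * X
  SC[, tot == 0] <- 0
  ic <- argmax2(SC)

  list(n_reads = nrow(r), abundance = sum(r$count),
       logodds = SA[ia[1], ia[2]], logodds_register = ia[1] - 1L,
       logodds_window = win_iv(ia[2]),
       pval = pw[jB], pval_register = rB, pval_window = win_iv(jB),
       ratio = SC[ic[1], ic[2]], ratio_register = ic[1] - 1L,
       ratio_window = win_iv(ic[2]))
}

#' Log-odds phasing score of a locus (Algorithm A)
#'
#' Maximum over sliding windows of `m` phase cycles and candidate registers
#' of [phase_logodds_score()], with reads 1 nt off-register counted in-phase
#' at weight `drift_weight`.
#'
#' @inheritParams register_profile
#' @param m window size in phase cycles (window spans `m * s` nt).
#' @param drift_weight weight of +/-1 nt off-register reads in P.
#' @return list with `score`, `register`, `window` (0-based half-open).
#' @export
phase_logodds <- function(lib, locus, s, m = 9, length_tolerance = 0,
                          drift_weight = 0.5) {
  stopifnot(m >= 3)
  sc <- phase_scan(lib, locus, s, m, length_tolerance, drift_weight)
  list(score = sc$logodds, register = sc$logodds_register,
       window = sc$logodds_window)
}

#' Hypergeometric phasing p-value of a locus (Algorithm B)
#'
#' Within each window of `m` cycles the N = m*s strand-collapsed positions
#' contain K = m in-register slots for each candidate register; with n
#' distinct occupied positions of which x are in-register, the p-value is
#' the hypergeometric upper tail P(X >= x). The minimum over windows and
#' registers is reported. No multiple-window or multiple-locus correction is
#' applied; callers wanting one can correct across loci afterwards.
#'
#' @inheritParams phase_logodds
#' @return list with `pval`, `register`, `window`.
#' @export
phase_hypergeom <- function(lib, locus, s, m = 10, length_tolerance = 0) {
  stopifnot(m >= 3)
  sc <- phase_scan(lib, locus, s, m, length_tolerance)
  list(pval = sc$pval, register = sc$pval_register, window = sc$pval_window)
}

#' Phased-ratio score of a locus (Algorithm C)
#'
#' `(P / (P + U)) * k` over the maximizing window and register, with exact
#' registers (no drift tolerance); 0 when the window is empty.
#'
#' @inheritParams phase_logodds
#' @return list with `score`, `register`, `window`.
#' @export
phase_ratio <- function(lib, locus, s, m = 9, length_tolerance = 0) {
  stopifnot(m >= 3)
  sc <- phase_scan(lib, locus, s, m, length_tolerance)
  list(score = sc$ratio, register = sc$ratio_register, window = sc$ratio_window)
}

#' All three phasing statistics for one locus in one library
#'
#' @inheritParams phase_logodds
#' @param m_logodds,m_hypergeom,m_ratio window sizes (cycles) per algorithm.
#' @return one-row data.frame: locus_id, library_id, phase_size,
#'   score_logodds, pval_hypergeom, score_ratio, dominant_register,
#'   dominant_fraction, n_reads, abundance, window bounds per algorithm.
#' @export
phase_locus <- function(lib, locus, s, m_logodds = 9, m_hypergeom = 10,
                        m_ratio = 9, length_tolerance = 0,
                        drift_weight = 0.5) {
  locus <- as_locus(locus)
  scA <- phase_scan(lib, locus, s, m_logodds, length_tolerance, drift_weight)
  scB <- if (m_hypergeom == m_logodds) scA else
    phase_scan(lib, locus, s, m_hypergeom, length_tolerance, drift_weight)
  scC <- if (m_ratio == m_logodds) scA else
    if (m_ratio == m_hypergeom) scB else
      phase_scan(lib, locus, s, m_ratio, length_tolerance, drift_weight)
  prof <- register_profile(lib, locus, s, length_tolerance)
  data.frame(
    locus_id = locus$locus_id %||% NA_character_,
    library_id = lib$library_id,
    phase_size = s,
    score_logodds = scA$logodds,
    pval_hypergeom = scB$pval,
    score_ratio = scC$ratio,
    dominant_register = prof$dominant_register,
    dominant_fraction = prof$dominant_fraction,
    n_reads = scA$n_reads,
    abundance = scA$abundance,
    logodds_window_start = scA$logodds_window[1],
    logodds_window_end = scA$logodds_window[2],
    pval_window_start = scB$pval_window[1],
    pval_window_end = scB$pval_window[2],
    ratio_window_start = scC$ratio_window[1],
    ratio_window_end = scC$ratio_window[2],
    stringsAsFactors = FALSE
  )
}

#' Phasing statistics for many loci across many libraries
#'
#' @param loci locus data.frame.
#' @param libs list of `srna_library` objects.
#' @inheritParams phase_locus
#' @return data.frame with one row per locus x library.
#' @export
phase_table <- function(loci, libs, s, m_logodds = 9, m_hypergeom = 10,
                        m_ratio = 9, length_tolerance = 0,
                        drift_weight = 0.5) {
  if (inherits(libs, "srna_library")) libs <- list(libs)
  out <- vector("list", nrow(loci) * length(libs))
  k <- 0L
  for (lib in libs) {
    idx <- assign_reads(lib, loci)
    for (i in seq_len(nrow(loci))) {
      sub <- srna_subset(lib, idx[[i]])
      k <- k + 1L
      out[[k]] <- phase_locus(sub, loci[i, ], s, m_logodds, m_hypergeom,
                              m_ratio, length_tolerance, drift_weight)
    }
  }
  do.call(rbind, out)
}

# Cheap library view holding only the given read rows (keeps total_primary).
srna_subset <- function(lib, rows) {
  structure(list(library_id = lib$library_id,
                 reads = if (is.null(rows)) lib$reads[0, , drop = FALSE]
                         else lib$reads[rows, , drop = FALSE],
                 total_primary = lib$total_primary),
            class = "srna_library")
}

#' Phase-register consistency of a locus across libraries
#'
#' A genuine PHAS locus should show the same dominant phase register in
#' every library, with the majority of its reads in that register. Reports
#' the per-library dominant registers, whether all non-empty libraries
#' agree, and whether every library clears the majority (> 0.5) criterion.
#'
#' @param locus one-row locus data.frame or list.
#' @param libs list of >= 2 `srna_library` objects.
#' @inheritParams register_profile
#' @return list with `per_library` data.frame (library_id, dominant_register,
#'   dominant_fraction, total), `consistent`, `majority`,
#'   `min_dominant_fraction`, `undetermined`.
#' @export
register_consistency <- function(locus, libs, s, length_tolerance = 0) {
  stopifnot(length(libs) >= 2)
  locus <- as_locus(locus)
  per <- do.call(rbind, lapply(libs, function(lib) {
    p <- register_profile(lib, locus, s, length_tolerance)
    data.frame(library_id = lib$library_id,
               dominant_register = p$dominant_register,
               dominant_fraction = p$dominant_fraction,
               total = p$total, stringsAsFactors = FALSE)
  }))
  nonempty <- per$total > 0
  undetermined <- !any(nonempty)
  consistent <- if (undetermined) NA else
    length(unique(per$dominant_register[nonempty])) == 1L
  majority <- all(per$dominant_fraction > 0.5)
  list(per_library = per, consistent = consistent, majority = majority,
       min_dominant_fraction = min(per$dominant_fraction),
       undetermined = undetermined)
}
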