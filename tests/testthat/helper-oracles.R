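# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# Exhaustive hypergeometric tail by bitmask enumeration: every subset of N
# positions is enumerated; for each occupancy size n the upper-tail
# P(X >= x) is the fraction of size-n subsets with at least x of the first
# K positions. Returns max |enumerated - f(x, N, K, n)| over all (n, x).
enum_hypergeom_max_diff <- function(N, K, f) {
  masks <- 0:(2^N - 1)
  pop <- function(v) {
    out <- integer(length(v))
    while (any(v > 0)) {
      out <- out + (v %% 2L)
      v <- v %/% 2L
    }
    out
  }
  n_all <- pop(masks)
  x_all <- pop(bitwAnd(masks, 2L^K - 1L))
  worst <- 0
  for (n in 0:N) {
    sel <- n_all == n
    xs <- x_all[sel]
    total <- sum(sel)
    for (x in 0:min(n, K)) {
      enum <- sum(xs >= x) / total
      worst <- max(worst, abs(enum - f(x, N, K, n)))
    }
  }
  worst
}

# combn-based enumeration for a single (N, K, n): positions 1..K are
# in-register; returns the enumerated tail for each x in 0..min(n, K).
enum_hypergeom_tail <- function(N, K, n) {
  if (n == 0) return(c(`0` = 1))
  sets <- utils::combn(N, n)
  x_per_set <- colSums(sets <= K)
  vapply(0:min(n, K), function(x) mean(x_per_set >= x), numeric(1))
}

# Position-by-position Hamming genome scan, both strands: for every window
# start, mismatches are accumulated one query offset at a time over the
# whole genome vector.
brute_scan_homologs <- function(genome_seq, query, max_mm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  g <- strsplit(toupper(genome_seq), "")[[1]]
  q <- strsplit(chartr("U", "T", toupper(query)), "")[[1]]
  L <- length(q)
  qrc <- rev(unname(comp[q]))
  nw <- length(g) - L + 1
  mm_p <- integer(nw)
  mm_m <- integer(nw)
  for (j in seq_len(L)) {
    seg <- g[j:(j + nw - 1)]
    mm_p <- mm_p + (seg != q[j])
    mm_m <- mm_m + (seg != qrc[j])
  }
  hp <- which(mm_p <= max_mm)
  hm <- which(mm_m <= max_mm)
  out <- rbind(
    data.frame(start = hp - 1L, strand = rep("+", length(hp)),
               n_mismatches = mm_p[hp]),
    data.frame(start = hm - 1L, strand = rep("-", length(hm)),
               n_mismatches = mm_m[hm])
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

# End-gap-free mismatch comparison of a query against collapsed reads.
brute_query_collapsed <- function(seqs, query, max_mm, len_tol) {
  query <- chartr("U", "T", toupper(query))
  vapply(seqs, function(sq) {
    sq <- chartr("U", "T", toupper(sq))
    if (abs(nchar(sq) - nchar(query)) > len_tol) return(FALSE)
    a <- strsplit(if (nchar(sq) <= nchar(query)) sq else query, "")[[1]]
    b <- strsplit(if (nchar(sq) <= nchar(query)) query else sq, "")[[1]]
    best <- Inf
    for (off in 0:(length(b) - length(a))) {
      best <- min(best, sum(a != b[(off + 1):(off + length(a))]))
    }
    best <= max_mm
  }, logical(1), USE.NAMES = FALSE)
}
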