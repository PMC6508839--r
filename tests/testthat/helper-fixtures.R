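# Fixture builders shared across tests. Everything is constructed in code;
# no data files.

# Library from parallel vectors; counts default to 1.
make_library <- function(start, length, strand, count = 1, chrom = "chr1",
                         n_placements = 1, library_id = "libA",
                         total_primary = NULL) {
  n <- max(lengths(list(start, length, strand)))
  srna_library(
    data.frame(chrom = chrom, start = start, length = length,
               strand = strand,
               count = rep_len(count, n),
               n_placements = rep_len(n_placements, n),
               stringsAsFactors = FALSE),
    library_id = library_id, total_primary = total_primary
  )
}

# A perfectly phased locus: reads at trigger + i*s on both strands with
# duplex geometry, plus optional off-register contamination.
make_phased_library <- function(trigger = 100, s = 21, n_cycles = 10,
                                count = 5, both_strands = TRUE,
                                library_id = "libA", total_primary = NULL) {
  pos <- trigger + s * (seq_len(n_cycles) - 1)
  start <- pos
  strand <- rep("+", n_cycles)
  if (both_strands) {
    start <- c(start, pos - 2L)
    strand <- c(strand, rep("-", n_cycles))
  }
  make_library(start, s, strand, count = count, library_id = library_id,
               total_primary = total_primary)
}

locus_around <- function(lib, pad = 10) {
  r <- lib$reads
  list(locus_id = "fixture", chrom = r$chrom[1],
       start = min(r$start) - pad, end = max(r$start + r$length) + pad)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
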