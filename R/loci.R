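# Locus definition: cluster alignments into intervals, call the dominant
# read size, and classify feature overlap.

reads_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L,
                              end = reads$start + reads$length),
    strand = "*"
  )
}

loci_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end)
  )
}

#' Cluster aligned reads into small RNA loci
#'
#' Maximal genomic intervals in which consecutive read footprints are
#' separated by at most `pad` nt, then filtered to drop loci whose summed
#' abundance is below `min_cov_rpm` reads per million of the library's
#' primary alignment total. Defaults mirror the standard sRNA locus
#' definition (pad 75 nt, floor 0.5 RPM).
#'
#' @param lib an `srna_library`.
#' @param pad maximum footprint gap (nt) bridged within one locus.
#' @param min_cov_rpm minimum locus abundance in RPM.
#' @return data.frame of non-overlapping loci sorted by (chrom, start) with
#'   columns locus_id, chrom, start, end, length, n_reads, abundance,
#'   abundance_rpm.
#' @export
cluster_loci <- function(lib, pad = 75, min_cov_rpm = 0.5) {
  stopifnot(inherits(lib, "srna_library"), pad >= 0, min_cov_rpm >= 0)
  r <- lib$reads
  if (!nrow(r)) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_reads = integer(), abundance = numeric(),
                      abundance_rpm = numeric(), stringsAsFactors = FALSE))
  }
  gr <- reads_granges(r)
  red <- GenomicRanges::reduce(gr, min.gapwidth = pad + 1L)
  red <- GenomicRanges::sort(red)
  hit <- GenomicRanges::findOverlaps(gr, red)
  ab <- rep(0, length(red))
  tab <- rowsum(r$count[S4Vectors::queryHits(hit)], S4Vectors::subjectHits(hit))
  ab[as.integer(rownames(tab))] <- tab[, 1]
  nr <- rep(0L, length(red))
  ntab <- table(S4Vectors::subjectHits(hit))
  nr[as.integer(names(ntab))] <- as.integer(ntab)
  loci <- data.frame(
    locus_id = sprintf("%s_locus_%05d", lib$library_id, seq_along(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_reads = nr,
    abundance = ab,
    abundance_rpm = rpm(ab, lib$total_primary),
    stringsAsFactors = FALSE
  )
  loci$length <- loci$end - loci$start
  loci <- loci[loci$abundance_rpm >= min_cov_rpm, , drop = FALSE]
  loci <- loci[order(loci$chrom, loci$start), c("locus_id", "chrom", "start",
                                                "end", "length", "n_reads",
                                                "abundance", "abundance_rpm")]
  rownames(loci) <- NULL
  loci
}

# Subset a library to reads whose footprint overlaps [start, end) on chrom.
reads_in_locus <- function(lib, chrom, start, end) {
  r <- lib$reads
  r[r$chrom == chrom & r$start < end & (r$start + r$length) > start, ,
    drop = FALSE]
}

# One findOverlaps pass assigning every read to the loci it overlaps;
# returns a list of read-row index vectors, one per locus row.
assign_reads <- function(lib, loci) {
  out <- vector("list", nrow(loci))
  if (!nrow(lib$reads) || !nrow(loci)) return(out)
  hit <- GenomicRanges::findOverlaps(reads_granges(lib$reads), loci_granges(loci))
  sp <- split(S4Vectors::queryHits(hit), S4Vectors::subjectHits(hit))
  out[as.integer(names(sp))] <- sp
  out
}

#' Call the dominant read size of each locus
#'
#' The dominant size is the read length carrying the greatest
#' abundance-weighted share of the locus; ties break toward the smaller
#' length and are flagged. A locus is conventionally called "s-dominated"
#' when the dominant size is s with share >= 0.5 (see [is_dominated()]).
#'
#' @param loci locus data.frame from [cluster_loci()].
#' @param lib the `srna_library` the sizes are tallied in.
#' @return `loci` with columns dominant_size, dominant_size_fraction and
#'   dominant_size_ambiguous appended.
#' @export
call_dominant_size <- function(loci, lib) {
  idx <- assign_reads(lib, loci)
  n <- nrow(loci)
  loci$dominant_size <- rep(NA_integer_, n)
  loci$dominant_size_fraction <- rep(0, n)
  loci$dominant_size_ambiguous <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ri <- idx[[i]]
    if (is.null(ri) || !length(ri)) next
    ab <- rowsum(lib$reads$count[ri], lib$reads$length[ri])
    lens <- as.integer(rownames(ab))
    best <- which(ab[, 1] == max(ab[, 1]))
    loci$dominant_size[i] <- min(lens[best])
    loci$dominant_size_fraction[i] <- max(ab[, 1]) / sum(ab[, 1])
    loci$dominant_size_ambiguous[i] <- length(best) > 1L
  }
  loci
}

#' Is a locus dominated by reads of size s?
#'
#' @param loci output of [call_dominant_size()].
#' @param s read length in nt.
#' @param min_fraction minimum abundance share for "dominated" (default 0.5).
#' @return logical vector.
#' @export
is_dominated <- function(loci, s, min_fraction = 0.5) {
  !is.na(loci$dominant_size) & loci$dominant_size == s &
    loci$dominant_size_fraction >= min_fraction
}

#' Classify loci by genomic feature overlap
#'
#' A locus intersecting at least one transposable-element feature is classed
#' `transposable_element` (TE priority: TE overlap is the hc-siRNA
#' signature); otherwise gene overlap gives `gene`; otherwise `intergenic`.
#'
#' @param loci locus data.frame.
#' @param features a [feature_set()].
#' @param priority class checked first when a locus overlaps both.
#' @return `loci` with a `feature_class` column appended.
#' @export
classify_overlap <- function(loci, features,
                             priority = "transposable_element") {
  stopifnot(inherits(features, "feature_set"))
  cls <- rep("intergenic", nrow(loci))
  if (nrow(features) && nrow(loci)) {
    fgr <- GenomicRanges::GRanges(features$chrom,
                                  IRanges::IRanges(features$start + 1L,
                                                   features$end))
    hit <- GenomicRanges::findOverlaps(loci_granges(loci), fgr)
    q <- S4Vectors::queryHits(hit)
    fcls <- features$class[S4Vectors::subjectHits(hit)]
    other <- setdiff(c("transposable_element", "gene"), priority)
    cls[unique(q[fcls == other])] <- other
    cls[unique(q[fcls == priority])] <- priority
  }
  loci$feature_class <- cls
  loci
}

#' Percentage of loci intersecting each feature class
#'
#' Computed as (number of loci intersecting a feature / total number of loci
#' in the group) * 100.
#'
#' @param loci output of [classify_overlap()].
#' @return named numeric vector over gene, transposable_element, intergenic.
#' @export
overlap_percentages <- function(loci) {
  stopifnot("feature_class" %in% names(loci))
  n <- nrow(loci)
  vapply(c(gene = "gene", transposable_element = "transposable_element",
           intergenic = "intergenic"),
         function(cl) if (n) 100 * sum(loci$feature_class == cl) / n else NA_real_,
         numeric(1))
}
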