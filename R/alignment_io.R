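#' Construct a small RNA alignment library
#'
#' The normalized in-memory model consumed by every downstream stage: one row
#' per distinct aligned species (chrom, start, length, strand), with `count`
#' holding the number of identical sequenced copies and `n_placements` the
#' number of equally good genomic placements (1 = unique-mapping).
#'
#' @param reads data.frame with columns `chrom` (character), `start`
#'   (0-based leftmost aligned base), `length` (read length in nt, 15-35),
#'   `strand` ("+" or "-"), `count` (>= 1) and optionally `n_placements`
#'   (>= 1, default 1). Rows sharing (chrom, start, length, strand) are
#'   aggregated by summing counts.
#' @param library_id label for the library.
#' @param total_primary total number of primary alignments in the library,
#'   the denominator for RPM. Defaults to `sum(reads$count)`.
#' @return an object of class `srna_library`.
#' @export
srna_library <- function(reads, library_id = "lib1", total_primary = NULL) {
  stopifnot(is.data.frame(reads))
  need <- c("chrom", "start", "length", "strand", "count")
  miss <- setdiff(need, names(reads))
  if (length(miss)) stop("reads is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(reads$n_placements)) reads$n_placements <- 1L
  if (nrow(reads)) {
    if (any(reads$start < 0)) stop("read start positions must be >= 0")
    if (any(reads$length < 15 | reads$length > 35)) {
      stop("read lengths must be within 15-35 nt")
    }
    if (any(reads$count < 1)) stop("read counts must be >= 1")
    if (any(reads$n_placements < 1)) stop("n_placements must be >= 1")
    if (!all(reads$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    reads <- aggregate_reads(reads)
  }
  if (is.null(total_primary)) total_primary <- max(1, sum(reads$count))
  if (total_primary < sum(reads$count)) {
    stop("total_primary must be >= the summed read count")
  }
  structure(
    list(library_id = library_id, reads = reads,
         total_primary = as.numeric(total_primary)),
    class = "srna_library"
  )
}

# Collapse identical (chrom, start, length, strand) rows; counts sum, the
# placement multiplicity takes the maximum seen.
aggregate_reads <- function(reads) {
  key <- paste(reads$chrom, reads$start, reads$length, reads$strand, sep = "\r")
  if (!anyDuplicated(key)) {
    out <- reads[, c("chrom", "start", "length", "strand", "count", "n_placements")]
  } else {
    first <- !duplicated(key)
    out <- reads[first, c("chrom", "start", "length", "strand", "count", "n_placements")]
    out$count <- as.numeric(rowsum(reads$count, key)[unique(key), 1])
    out$n_placements <- as.integer(tapply(reads$n_placements, key, max)[unique(key)])
  }
  out <- out[order(out$chrom, out$start, out$length, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library> %s: %d distinct reads, %s copies, %s primary alignments\n",
              x$library_id, nrow(x$reads),
              format(sum(x$reads$count), big.mark = ","),
              format(x$total_primary, big.mark = ",")))
  invisible(x)
}

#' Read primary small RNA alignments from a SAM or BAM file
#'
#' Secondary and supplementary records are ignored. The placement
#' multiplicity is taken from the standard `NH` tag when present, else 1.
#' `total_primary` is the number of primary aligned records.
#'
#' @param path SAM or BAM file.
#' @param library_id label; defaults to the file base name.
#' @return an `srna_library`.
#' @export
read_alignments <- function(path, library_id = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.null(library_id)) {
    library_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM file '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("rname", "pos", "strand", "qwidth"),
    tag = "NH"
  )
  res <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e) stop("unreadable alignment file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  n <- length(res$pos)
  if (n == 0L) stop("no aligned primary records in '", path, "'")
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(1L, n)
  nh[is.na(nh)] <- 1L
  reads <- data.frame(
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    length = res$qwidth,
    strand = as.character(res$strand),
    count = 1,
    n_placements = as.integer(nh),
    stringsAsFactors = FALSE
  )
  bad <- reads$length < 15 | reads$length > 35 | is.na(reads$length)
  if (any(bad)) {
    warning(sum(bad), " records outside the 15-35 nt small RNA range dropped ",
            "(still counted in total_primary)")
    reads <- reads[!bad, , drop = FALSE]
  }
  if (!nrow(reads)) stop("no usable small RNA records in '", path, "'")
  srna_library(reads, library_id = library_id, total_primary = n)
}

#' Write a library as a minimal SAM file
#'
#' Each distinct read is written `count` times so that re-reading with
#' [read_alignments()] reproduces the same (chrom, start, length, strand,
#' count) multiset; placement multiplicity is carried in the `NH` tag.
#'
#' @param lib an `srna_library`.
#' @param path output SAM path.
#' @param seqlengths named vector of reference lengths; defaults to the
#'   maximum footprint end per chromosome.
#' @return `path`, invisibly.
#' @export
write_sam <- function(lib, path, seqlengths = NULL) {
  stopifnot(inherits(lib, "srna_library"))
  r <- lib$reads
  if (is.null(seqlengths)) {
    ends <- tapply(r$start + r$length, r$chrom, max)
    seqlengths <- setNames(as.integer(ends), names(ends))
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  idx <- rep(seq_len(nrow(r)), times = r$count)
  rr <- r[idx, , drop = FALSE]
  body <- sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNH:i:%d",
                  seq_along(idx),
                  ifelse(rr$strand == "+", 0L, 16L),
                  rr$chrom, rr$start + 1L, rr$length,
                  vapply(rr$length, function(l) strrep("N", l), ""),
                  rr$n_placements)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reads per million
#'
#' @param count summed read count (>= 0).
#' @param total_primary primary alignment total (>= 1).
#' @return `count * 1e6 / total_primary`.
#' @export
rpm <- function(count, total_primary) {
  if (any(total_primary < 1)) stop("total_primary must be >= 1")
  if (any(count < 0)) stop("count must be >= 0")
  count * 1e6 / total_primary
}

# Default mapping from annotation feature types to the three classes the
# overlap analysis distinguishes.
default_class_map <- c(
  gene = "gene", mRNA = "gene", protein_coding_gene = "gene",
  transposable_element = "transposable_element",
  transposable_element_gene = "transposable_element",
  transposon_fragment = "transposable_element",
  TE = "transposable_element", repeat_region = "transposable_element"
)

#' Read genomic features from GFF3 or BED
#'
#' Coordinates are converted to the internal 0-based half-open convention
#' (GFF3 is 1-based inclusive; BED is already 0-based half-open). The
#' feature class is mapped from the GFF3 `type` (or BED name) column via
#' `class_map`; unmapped types become `"other"`.
#'
#' @param path GFF3/GFF or BED file.
#' @param class_map named character vector mapping feature types to classes
#'   in `c("gene", "transposable_element", "other")`.
#' @return data.frame with columns chrom, start, end, type, class.
#' @export
read_features <- function(path, class_map = default_class_map) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext %in% c("gff", "gff3", "gtf")) "gff3" else if (ext == "bed") "bed"
         else stop("unrecognised feature format: .", ext)
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  type <- if (fmt == "gff3") as.character(gr$type) else as.character(gr$name %||% "")
  cls <- unname(class_map[type])
  cls[is.na(cls)] <- "other"
  feature_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = type,
    class = cls,
    stringsAsFactors = FALSE
  ))
}

#' Construct a feature set from a data.frame
#'
#' @param features data.frame with columns chrom, start, end (0-based
#'   half-open) and class.
#' @return the validated data.frame, classed `feature_set`.
#' @export
feature_set <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("chrom", "start", "end", "class") %in% names(features)))
  if (nrow(features) && any(features$start >= features$end)) {
    stop("feature spans must satisfy start < end")
  }
  class(features) <- c("feature_set", "data.frame")
  features
}
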