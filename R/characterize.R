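# Locus-property metrics and random negative cohorts.

#' Sample random locus cohorts
#'
#' Draws `n_cohorts` cohorts of `cohort_size` loci from a pool, with
#' replacement both within and across cohorts by default — the standard
#' negative-control construction when comparing a small pass group against
#' the bulk of loci. Deterministic given the seed and pool order.
#'
#' @param pool locus data.frame (the sampling pool).
#' @param n_cohorts number of cohorts (default 10).
#' @param cohort_size loci per cohort (default 20).
#' @param with_replacement sample with replacement (default TRUE).
#' @param seed RNG seed.
#' @return list of data.frames, one per cohort.
#' @export
sample_cohorts <- function(pool, n_cohorts = 10, cohort_size = 20,
                           with_replacement = TRUE, seed = 1) {
  stopifnot(is.data.frame(pool), nrow(pool) >= 1,
            n_cohorts >= 1, cohort_size >= 1)
  if (!with_replacement && cohort_size > nrow(pool)) {
    stop("cohort_size exceeds pool size without replacement")
  }
  with_seed(seed, {
    lapply(seq_len(n_cohorts), function(i) {
      idx <- sample.int(nrow(pool), cohort_size, replace = with_replacement)
      out <- pool[idx, , drop = FALSE]
      rownames(out) <- NULL
      out
    })
  })
}

#' Per-locus property metrics in one library
#'
#' @param locus one-row locus data.frame or list with chrom, start, end.
#' @param lib an `srna_library`.
#' @return list with `length` (nt), `abundance` (read count),
#'   `abundance_rpm`, `multimap_fraction` (abundance-weighted fraction of
#'   reads with more than one placement), `size_histogram`
#'   (abundance-weighted proportions by read length, named by length), and
#'   `no_data` flag.
#' @export
locus_metrics <- function(locus, lib) {
  locus <- as_locus(locus)
  r <- reads_in_locus(lib, locus$chrom, locus$start, locus$end)
  len <- locus$end - locus$start
  if (!nrow(r)) {
    return(list(length = len, abundance = 0, abundance_rpm = 0,
                multimap_fraction = 0, size_histogram = numeric(0),
                no_data = TRUE))
  }
  ab <- sum(r$count)
  hist <- rowsum(r$count, r$length)
  list(
    length = len,
    abundance = ab,
    abundance_rpm = rpm(ab, lib$total_primary),
    multimap_fraction = sum(r$count[r$n_placements > 1]) / ab,
    size_histogram = setNames(hist[, 1] / ab, rownames(hist)),
    no_data = FALSE
  )
}

#' Metrics for every locus in a table
#'
#' @param loci locus data.frame.
#' @param lib an `srna_library`.
#' @return `loci` with abundance_rpm (recomputed in `lib`) and
#'   multimap_fraction columns.
#' @export
loci_metrics <- function(loci, lib) {
  idx <- assign_reads(lib, loci)
  loci$abundance_rpm <- vapply(seq_len(nrow(loci)), function(i) {
    ri <- idx[[i]]
    if (is.null(ri)) 0 else rpm(sum(lib$reads$count[ri]), lib$total_primary)
  }, numeric(1))
  loci$multimap_fraction <- vapply(seq_len(nrow(loci)), function(i) {
    ri <- idx[[i]]
    if (is.null(ri) || !length(ri)) return(0)
    ab <- sum(lib$reads$count[ri])
    sum(lib$reads$count[ri][lib$reads$n_placements[ri] > 1]) / ab
  }, numeric(1))
  loci
}

#' Five-number summaries of a pass group against cohorts
#'
#' Box-plot style summaries (median, 1st and 3rd quartile, whiskers out to
#' 1.5 times the interquartile range) per group. Quartiles use linear
#' interpolation (type-7). No significance test is attached.
#'
#' @param group_values named list of numeric vectors, one per group (e.g.
#'   the pass group plus each cohort).
#' @return data.frame with group, n, median, q1, q3, whisker_lo, whisker_hi.
#' @export
compare_groups <- function(group_values) {
  stopifnot(is.list(group_values), length(group_values) >= 1)
  if (is.null(names(group_values))) {
    names(group_values) <- paste0("group", seq_along(group_values))
  }
  rows <- lapply(names(group_values), function(g) {
    x <- group_values[[g]]
    if (!length(x)) stop("group '", g, "' is empty")
    q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    inlo <- x[x >= q[1] - 1.5 * iqr]
    inhi <- x[x <= q[3] + 1.5 * iqr]
    data.frame(group = g, n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(inlo), whisker_hi = max(inhi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
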