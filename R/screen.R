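# Cutoff calibration from positive-control loci and the multi-library,
# multi-algorithm consensus screen.

#' Calibrate pass cutoffs from positive-control phasing results
#'
#' Score cutoffs are set at the `quantile`-th linear-interpolated percentile
#' of the positive-control score distributions, so that about
#' `1 - quantile` of controls pass each detector. The type-6 interpolation
#' rule (`h = (n+1)p`) is used because its coverage is unbiased: on new
#' loci drawn from the control distribution the expected fraction below the
#' cutoff equals `quantile`, which is the point of the calibration; the p-value cutoff is the
#' `(1 - quantile)`-th percentile of the control p-values, capped at 0.05.
#' Because a control "passes" the screen only when it passes in every
#' library, each control locus is first summarized by its weakest library
#' (minimum score, maximum p-value) and the quantile is taken over those
#' per-locus summaries; set `per_locus = FALSE` to calibrate on the pooled
#' locus-by-library cells instead.
#'
#' @param positive_results [phase_table()] output for known PHAS loci
#'   (>= 5 rows).
#' @param quantile calibration quantile (default 0.05).
#' @param per_locus summarize each control locus by its weakest library
#'   before taking quantiles (default TRUE).
#' @return an object of class `phas_cutoffs`: list with `cutoff_logodds`,
#'   `cutoff_pval`, `cutoff_ratio`, `quantile`, `provenance`.
#' @export
calibrate_cutoffs <- function(positive_results, quantile = 0.05,
                              per_locus = TRUE) {
  if (is.null(positive_results) || !nrow(positive_results)) {
    stop("no positive-control results; supply explicit cutoffs via phas_cutoffs()")
  }
  stopifnot(quantile > 0, quantile < 1)
  if (nrow(positive_results) < 5) {
    stop("need >= 5 positive-control results to calibrate")
  }
  scores_lo <- positive_results$score_logodds
  pvals <- positive_results$pval_hypergeom
  scores_ra <- positive_results$score_ratio
  if (per_locus && anyDuplicated(positive_results$locus_id)) {
    id <- positive_results$locus_id
    scores_lo <- as.numeric(tapply(scores_lo, id, min))
    pvals <- as.numeric(tapply(pvals, id, max))
    scores_ra <- as.numeric(tapply(scores_ra, id, min))
  }
  qt6 <- function(x, p) unname(stats::quantile(x, p, type = 6, names = FALSE))
  phas_cutoffs(
    cutoff_logodds = qt6(scores_lo, quantile),
    cutoff_pval = min(qt6(pvals, 1 - quantile), 0.05),
    cutoff_ratio = qt6(scores_ra, quantile),
    quantile = quantile,
    provenance = sprintf(
      "calibrated from %d positive-control results across %d libraries at quantile %g",
      nrow(positive_results),
      length(unique(positive_results$library_id)), quantile)
  )
}

#' Explicit phasing cutoffs
#'
#' @param cutoff_logodds minimum passing log-odds score (>= 0).
#' @param cutoff_pval maximum passing hypergeometric p-value in (0, 1].
#' @param cutoff_ratio minimum passing ratio score (>= 0).
#' @param quantile calibration quantile, if any.
#' @param provenance free-text description of where the cutoffs came from.
#' @return an object of class `phas_cutoffs`.
#' @export
phas_cutoffs <- function(cutoff_logodds, cutoff_pval, cutoff_ratio,
                         quantile = NA_real_, provenance = "explicit") {
  stopifnot(cutoff_logodds >= 0, cutoff_ratio >= 0,
            cutoff_pval > 0, cutoff_pval <= 1)
  structure(list(cutoff_logodds = cutoff_logodds, cutoff_pval = cutoff_pval,
                 cutoff_ratio = cutoff_ratio, quantile = quantile,
                 provenance = provenance),
            class = "phas_cutoffs")
}

#' @export
print.phas_cutoffs <- function(x, ...) {
  cat(sprintf("<phas_cutoffs> logodds >= %.4g, p <= %.4g, ratio >= %.4g (%s)\n",
              x$cutoff_logodds, x$cutoff_pval, x$cutoff_ratio, x$provenance))
  invisible(x)
}

#' Run the multi-algorithm, multi-library consensus screen
#'
#' Every locus is evaluated by the three phasing detectors in every library.
#' A cell passes per its cutoff; a locus with no eligible reads in a library
#' fails all three cells there (recorded as no-data). The consensus flag
#' requires every one of the 3 x L cells to pass. Venn tallies count loci
#' that pass a detector in all libraries, by detector subset.
#'
#' @param loci locus data.frame (called at dominant size `s`).
#' @param libs list of `srna_library` objects.
#' @param s phase size in nt.
#' @param cutoffs a `phas_cutoffs` object.
#' @inheritParams phase_table
#' @return an object of class `phas_screen`: list with `results` (the full
#'   phase table with pass columns), `pass` (locus x library x detector
#'   logical array), `all_lib_pass` (locus x detector matrix), `consensus`
#'   (logical per locus), `venn` (named counts by detector subset),
#'   `cutoffs`, `s`, `library_ids`, `loci`.
#' @export
screen_loci <- function(loci, libs, s, cutoffs, m_logodds = 9,
                        m_hypergeom = 10, m_ratio = 9, length_tolerance = 0,
                        drift_weight = 0.5) {
  stopifnot(inherits(cutoffs, "phas_cutoffs"), length(libs) >= 1)
  if (inherits(libs, "srna_library")) libs <- list(libs)
  res <- phase_table(loci, libs, s, m_logodds, m_hypergeom, m_ratio,
                     length_tolerance, drift_weight)
  res$no_data <- res$n_reads == 0
  res$pass_logodds <- !res$no_data & res$score_logodds >= cutoffs$cutoff_logodds
  res$pass_pval <- !res$no_data & res$pval_hypergeom <= cutoffs$cutoff_pval
  res$pass_ratio <- !res$no_data & res$score_ratio >= cutoffs$cutoff_ratio
  nl <- nrow(loci)
  L <- length(libs)
  lib_ids <- vapply(libs, function(x) x$library_id, "")
  detectors <- c("logodds", "pval", "ratio")
  pass <- array(FALSE, dim = c(nl, L, 3),
                dimnames = list(loci$locus_id, lib_ids, detectors))
  # phase_table iterates libraries outer, loci inner
  for (d in seq_along(detectors)) {
    pass[, , d] <- matrix(res[[paste0("pass_", detectors[d])]],
                          nrow = nl, ncol = L)
  }
  all_lib_pass <- apply(pass, c(1, 3), all)
  if (nl == 1L) all_lib_pass <- matrix(all_lib_pass, nrow = 1,
                                       dimnames = list(loci$locus_id, detectors))
  consensus <- apply(all_lib_pass, 1, all)
  venn <- venn_tally(all_lib_pass)
  structure(list(results = res, pass = pass, all_lib_pass = all_lib_pass,
                 consensus = consensus, venn = venn, cutoffs = cutoffs,
                 s = s, library_ids = lib_ids, loci = loci),
            class = "phas_screen")
}

# Count loci by the subset of detectors they pass in all libraries.
venn_tally <- function(all_lib_pass) {
  detectors <- colnames(all_lib_pass)
  combos <- unlist(lapply(seq_along(detectors), function(k) {
    apply(utils::combn(detectors, k), 2, paste, collapse = "&")
  }))
  counts <- setNames(integer(length(combos)), combos)
  lab <- apply(all_lib_pass, 1, function(row) {
    paste(detectors[row], collapse = "&")
  })
  tab <- table(lab[lab != ""])
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' @export
print.phas_screen <- function(x, ...) {
  cat(sprintf("<phas_screen> %d loci x %d libraries at s = %d: %d consensus pass\n",
              nrow(x$loci), length(x$library_ids), x$s, sum(x$consensus)))
  cat("Venn (pass in all libraries): ",
      paste(sprintf("%s=%d", names(x$venn), x$venn), collapse = ", "), "\n")
  invisible(x)
}

#' Post-hoc diagnostics for consensus-passing loci
#'
#' Applies the checks that separate genuine PHAS loci from highly expressed
#' hc-siRNA loci that slip through the detectors: phase-register consistency
#' across libraries, the majority-register criterion in every library,
#' feature-class overlap, and the locus properties (length, RPM, multimapping
#' proportion). The verdict is `"PHAS-supported"` only when the register is
#' consistent and the majority criterion holds in all libraries.
#'
#' @param report a `phas_screen` from [screen_loci()].
#' @param libs the same library list the screen used.
#' @param features optional [feature_set()] for overlap classification.
#' @param which row indices of loci to diagnose; defaults to the
#'   consensus-passing set.
#' @inheritParams register_profile
#' @return data.frame with one row per diagnosed locus: locus_id,
#'   feature_class, length, abundance_rpm, multimap_fraction,
#'   register_consistent, majority_all_libraries, min_dominant_fraction,
#'   verdict.
#' @export
diagnose_screen <- function(report, libs, features = NULL,
                            which = NULL, length_tolerance = 0) {
  stopifnot(inherits(report, "phas_screen"))
  loci <- report$loci
  if (is.null(which)) which <- which(report$consensus)
  if (!length(which)) {
    return(data.frame(locus_id = character(), feature_class = character(),
                      length = integer(), abundance_rpm = numeric(),
                      multimap_fraction = numeric(),
                      register_consistent = logical(),
                      majority_all_libraries = logical(),
                      min_dominant_fraction = numeric(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  sub <- loci[which, , drop = FALSE]
  if (!is.null(features)) sub <- classify_overlap(sub, features)
  else sub$feature_class <- NA_character_
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    locus <- sub[i, ]
    rc <- register_consistency(locus, libs, report$s, length_tolerance)
    met <- pooled_metrics(locus, libs)
    supported <- isTRUE(rc$consistent) && rc$majority
    data.frame(locus_id = locus$locus_id,
               feature_class = locus$feature_class,
               length = locus$end - locus$start,
               abundance_rpm = met$abundance_rpm,
               multimap_fraction = met$multimap_fraction,
               register_consistent = rc$consistent,
               majority_all_libraries = rc$majority,
               min_dominant_fraction = rc$min_dominant_fraction,
               verdict = if (supported) "PHAS-supported" else "not-PHAS-supported",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Abundance-weighted locus metrics pooled across libraries.
pooled_metrics <- function(locus, libs) {
  ms <- lapply(libs, function(lib) locus_metrics(locus, lib))
  ab <- vapply(ms, function(m) m$abundance, numeric(1))
  w <- if (sum(ab) > 0) ab / sum(ab) else rep(1 / length(ms), length(ms))
  list(
    abundance_rpm = sum(w * vapply(ms, function(m) m$abundance_rpm, numeric(1))),
    multimap_fraction = sum(w * vapply(ms, function(m) m$multimap_fraction,
                                       numeric(1)))
  )
}
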