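# Ground-truthed synthetic small RNA scenes: true PHAS loci with tunable
# in-register precision, imprecise heterochromatic-siRNA (hc-siRNA) loci,
# multi-library resampling of the same loci, and planted miRNA hairpins.

#' Parameters of a simulated PHAS locus
#'
#' A true PHAS locus emits reads at s-nt increments from a defined trigger
#' position on both strands with 2-nt 3'-overhang duplex geometry. Each read
#' is exactly in register with probability `precision`, else its 5' end is
#' shifted by +/- 1..`jitter` nt. Per-position abundance is log-normal and
#' locus-intrinsic, so independent libraries resample the same hotspots.
#'
#' @param phase_size s in nt (21 or 24).
#' @param n_cycles number of phase positions (>= 3, default 10).
#' @param trigger_register desired register (0..s-1) of the trigger; NULL
#'   leaves it to the placement.
#' @param precision probability a read is exactly in register (default 0.95).
#' @param jitter maximum off-register shift in nt (default 3).
#' @param mean_reads_per_library expected sampled reads per library
#'   (default 60).
#' @param strand_balance fraction of reads on the plus strand (default 0.5).
#' @param offphase_fraction fraction of reads emitted as uniform off-phase
#'   background over the locus (default 0). Real PHAS loci carry such a
#'   background (degradation fragments, transitive spreading, overlapping
#'   siRNA populations); a genuine locus shows a majority (> 0.5), not a
#'   purity, of reads in its dominant register.
#' @param abundance_sdlog log-normal sd of per-position abundance weights.
#' @return an object of class `phas_locus_params`.
#' @export
phas_params <- function(phase_size = 21, n_cycles = 10,
                        trigger_register = NULL, precision = 0.95,
                        jitter = 3, mean_reads_per_library = 60,
                        strand_balance = 0.5, offphase_fraction = 0,
                        abundance_sdlog = 0.8) {
  stopifnot(phase_size %in% c(21, 24), n_cycles >= 3,
            precision >= 0, precision <= 1, jitter >= 1,
            strand_balance >= 0, strand_balance <= 1,
            offphase_fraction >= 0, offphase_fraction < 1)
  structure(list(class = "PHAS", phase_size = phase_size, n_cycles = n_cycles,
                 trigger_register = trigger_register, precision = precision,
                 jitter = jitter,
                 mean_reads_per_library = mean_reads_per_library,
                 strand_balance = strand_balance,
                 offphase_fraction = offphase_fraction,
                 abundance_sdlog = abundance_sdlog),
            class = "phas_locus_params")
}

#' Parameters of a simulated hc-siRNA locus
#'
#' hc-siRNA loci emit imprecisely positioned, 24-nt-dominated reads over
#' intervals of tunable length and expression. Under `uniform` placement 5'
#' positions are i.i.d. uniform over the locus (the exchangeable null the
#' phasing statistics assume); under `clustered` placement reads come from
#' log-normal-weighted hotspot islands, the realistic stress test.
#'
#' @param length locus length in nt (>= 100).
#' @param expression_rpm target abundance in reads per million.
#' @param size_distribution named read-length probabilities (default 80%
#'   mass at 24 nt).
#' @param placement "uniform" or "clustered".
#' @param multimap_fraction fraction of reads flagged as multimapping.
#' @param position_density distinct catalogue read species per nt under
#'   `clustered` placement (default 1/15: one recurrent 5' position every
#'   ~15 nt, as seen at strongly expressed heterochromatic loci).
#' @param abundance_sdlog log-normal sd of catalogue species abundances
#'   (default 2: species abundances span 3-4 orders of magnitude, the skew
#'   typical of sRNA-seq loci).
#' @return an object of class `hc_locus_params`.
#' @export
hc_params <- function(length = 2000, expression_rpm = 10,
                      size_distribution = c("21" = 0.05, "22" = 0.05,
                                            "23" = 0.10, "24" = 0.80),
                      placement = c("uniform", "clustered"),
                      multimap_fraction = 0.1, position_density = 1 / 15,
                      abundance_sdlog = 2) {
  placement <- match.arg(placement)
  stopifnot(length >= 100, expression_rpm > 0,
            abs(sum(size_distribution) - 1) < 1e-9,
            multimap_fraction >= 0, multimap_fraction <= 1,
            position_density > 0)
  structure(list(class = "HC", length = length,
                 expression_rpm = expression_rpm,
                 size_distribution = size_distribution,
                 placement = placement,
                 multimap_fraction = multimap_fraction,
                 position_density = position_density,
                 abundance_sdlog = abundance_sdlog),
            class = "hc_locus_params")
}

#' A cohort of PHAS locus parameter sets with realistic expression spread
#'
#' Real PHAS loci span orders of magnitude in expression; a cohort of
#' identically expressed loci would make calibration quantiles meaningless.
#' Per-locus mean reads per library are log-normal with a floor.
#'
#' @param n number of loci.
#' @param median_reads median mean-reads-per-library across the cohort.
#' @param sdlog log-sd of the spread.
#' @param floor_reads minimum mean reads per library.
#' @param seed RNG seed for the expression draw.
#' @param ... further arguments passed to [phas_params()].
#' @return list of `phas_locus_params`.
#' @export
phas_cohort <- function(n, median_reads = 60, sdlog = 0.75, floor_reads = 30,
                        seed = 1, ...) {
  means <- with_seed(seed, {
    pmax(floor_reads, rlnorm(n, log(median_reads), sdlog))
  })
  lapply(means, function(m) phas_params(mean_reads_per_library = m, ...))
}

#' Simulate a genome scene with ground truth
#'
#' Places the requested loci (and optional planted miRNA hairpins) along a
#' synthetic chromosome without overlap, draws each locus's intrinsic
#' per-position abundance weights, and returns the scene every
#' [sample_library()] call resamples. Deterministic given the seed.
#'
#' @param loci list of [phas_params()] / [hc_params()] objects.
#' @param genome_length chromosome length in nt.
#' @param seed RNG seed.
#' @param chrom chromosome name.
#' @param hairpins optional list of `list(mature = <sequence>,
#'   n_mismatches = <k>)`: each plants a perfect inverted-repeat hairpin
#'   whose mature arm differs from `mature` by exactly `n_mismatches`
#'   substitutions.
#' @param gap minimum spacing between placed elements (nt).
#' @param emit_sequence generate the genome sequence (required when
#'   hairpins are planted; can be FALSE for phasing-only scenes).
#' @return an object of class `phas_scene`: list with `genome`
#'   (`DNAStringSet` or NULL), `seqlengths`, `truth` (locus data.frame with
#'   class, span, phase size, trigger), `params`, `weights`, `hairpins`
#'   (data.frame of planted mature coordinates), `seed`.
#' @export
simulate_scene <- function(loci, genome_length, seed = 1, chrom = "chrSim",
                           hairpins = list(), gap = 200,
                           emit_sequence = TRUE) {
  stopifnot(is.list(loci), length(loci) >= 1 || length(hairpins) >= 1)
  if (length(hairpins) && !emit_sequence) {
    stop("planting hairpins requires emit_sequence = TRUE")
  }
  widths <- vapply(loci, function(p) {
    if (inherits(p, "phas_locus_params")) {
      p$n_cycles * p$phase_size + 2 * (2 + p$jitter)
    } else if (inherits(p, "hc_locus_params")) p$length
    else stop("loci entries must be phas_params() or hc_params() objects")
  }, numeric(1))
  hp_seqs <- lapply(hairpins, function(h) h)  # validated below
  hp_widths <- vapply(hairpins, function(h) {
    2 * nchar(norm_dna(h$mature)) + 2 * 40 + 8
  }, numeric(1))
  k <- length(widths) + length(hp_widths)
  total <- sum(widths) + sum(hp_widths) + gap * (k + 1)
  if (total > genome_length) {
    stop(sprintf("loci do not fit genome: need >= %d nt, have %d",
                 ceiling(total), genome_length))
  }
  with_seed(seed, {
    slack <- genome_length - total
    extra <- if (slack > 0) {
      as.vector(rmultinom(1, size = floor(slack), prob = rep(1, k + 1)))
    } else rep(0, k + 1)
    all_w <- c(widths, hp_widths)
    starts <- numeric(k)
    pos <- 0
    for (i in seq_len(k)) {
      pos <- pos + gap + extra[i]
      starts[i] <- pos
      pos <- pos + all_w[i]
    }
    truth <- NULL
    weights <- vector("list", length(loci))
    if (length(loci)) {
      truth <- data.frame(
        locus_id = sprintf("truth_%04d", seq_along(loci)),
        class = vapply(loci, function(p) p$class, ""),
        chrom = chrom,
        start = as.integer(starts[seq_along(loci)]),
        end = as.integer(starts[seq_along(loci)] + widths),
        stringsAsFactors = FALSE
      )
      truth$phase_size <- NA_integer_
      truth$trigger <- NA_integer_
      for (i in seq_along(loci)) {
        p <- loci[[i]]
        if (inherits(p, "phas_locus_params")) {
          s <- p$phase_size
          trig <- truth$start[i] + 2 + p$jitter
          if (!is.null(p$trigger_register)) {
            trig <- trig + (p$trigger_register - trig) %% s
          }
          truth$phase_size[i] <- s
          truth$trigger[i] <- trig
          w <- matrix(rlnorm(2 * p$n_cycles, 0, p$abundance_sdlog),
                      nrow = 2)
          w[1, ] <- w[1, ] * p$strand_balance
          w[2, ] <- w[2, ] * (1 - p$strand_balance)
          weights[[i]] <- w
        } else if (p$placement == "clustered") {
          # Locus-intrinsic catalogue of exact read species: hc-siRNA
          # precursors have defined termini, so the same 5' positions recur
          # with skewed (log-normal) abundance in every library. Positions
          # fall in hotspot islands laid down by a seeded renewal walk.
          n_isl <- max(1L, rpois(1, p$length / 500))
          centers <- sort(runif(n_isl, 0, p$length))
          isl_w <- rlnorm(n_isl, 0, 1)
          n_pos <- max(4L, round(p$length * p$position_density))
          isl <- sample.int(n_isl, n_pos, replace = TRUE, prob = isl_w)
          lens <- as.integer(sample(names(p$size_distribution), n_pos,
                                    replace = TRUE,
                                    prob = p$size_distribution))
          rel <- round(centers[isl] + runif(n_pos, -1, 1) * 40)
          rel <- pmax(0, pmin(rel, p$length - lens))
          weights[[i]] <- data.frame(
            rel = as.integer(rel), length = lens,
            strand = sample(c("+", "-"), n_pos, replace = TRUE),
            w = rlnorm(n_pos, 0, p$abundance_sdlog),
            n_placements = ifelse(runif(n_pos) < p$multimap_fraction,
                                  sample(2:5, n_pos, replace = TRUE), 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
    hp_truth <- NULL
    genome <- NULL
    if (emit_sequence) {
      base <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
      if (length(hairpins)) {
        hp_rows <- vector("list", length(hairpins))
        for (j in seq_along(hairpins)) {
          h <- hairpins[[j]]
          mature <- norm_dna(h$mature)
          n_mm <- h$n_mismatches %||% 0L
          planted <- mutate_sequence(mature, n_mm)
          star <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(planted)))
          flank1 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
          flank2 <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
          loop <- paste(sample(c("A", "C"), 8, TRUE), collapse = "")
          block <- paste0(flank1, star, loop, planted, flank2)
          b0 <- starts[length(loci) + j]
          base[(b0 + 1):(b0 + nchar(block))] <- strsplit(block, "")[[1]]
          m0 <- b0 + 40 + nchar(planted) + 8
          hp_rows[[j]] <- data.frame(
            chrom = chrom, start = as.integer(m0),
            end = as.integer(m0 + nchar(planted)), strand = "+",
            n_mismatches = as.integer(n_mm), planted_sequence = planted,
            query_sequence = mature, stringsAsFactors = FALSE)
        }
        hp_truth <- do.call(rbind, hp_rows)
      }
      genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
      names(genome) <- chrom
    }
    structure(list(genome = genome,
                   seqlengths = setNames(genome_length, chrom),
                   chrom = chrom, truth = truth, params = loci,
                   weights = weights, hairpins = hp_truth, seed = seed),
              class = "phas_scene")
  })
}

# Apply exactly n substitutions at distinct positions.
mutate_sequence <- function(seq, n_mm) {
  if (n_mm == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n_mm)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' @export
print.phas_scene <- function(x, ...) {
  nl <- if (is.null(x$truth)) 0L else nrow(x$truth)
  cat(sprintf("<phas_scene> %s (%s nt): %d loci (%d PHAS, %d HC), %d planted hairpins\n",
              x$chrom, format(unname(x$seqlengths), big.mark = ","), nl,
              if (nl) sum(x$truth$class == "PHAS") else 0L,
              if (nl) sum(x$truth$class == "HC") else 0L,
              if (is.null(x$hairpins)) 0L else nrow(x$hairpins)))
  invisible(x)
}

#' Sample one small RNA library from a scene
#'
#' Per-locus read totals are multinomial over expression weights (PHAS loci
#' weighted by `mean_reads_per_library`, hc loci by
#' `expression_rpm * depth / 1e6`). PHAS loci emit duplex-geometry reads at
#' trigger + i*s with the locus's in-register precision; hc loci emit
#' imprecise reads with lengths from their size distribution. `depth` is the
#' library's primary alignment total (the RPM denominator); reads outside
#' the simulated loci make up the unemitted remainder.
#'
#' @param scene a `phas_scene`.
#' @param library_id label for the library.
#' @param depth total primary alignments (default 1e7, a typical mapped
#'   sRNA-seq library).
#' @param seed RNG seed (use a different seed per library).
#' @param expression_noise_sdlog log-sd of per-locus expression variation
#'   between libraries (default 0.4; biological replicates of sRNA loci
#'   commonly vary severalfold in RPM).
#' @return an `srna_library` with `total_primary = depth`.
#' @export
sample_library <- function(scene, library_id = "lib1", depth = 1e7, seed = 1,
                           expression_noise_sdlog = 0.4) {
  stopifnot(inherits(scene, "phas_scene"), depth >= 1)
  truth <- scene$truth
  if (is.null(truth) || !nrow(truth)) {
    stop("scene contains no loci to sample")
  }
  expected <- vapply(seq_len(nrow(truth)), function(i) {
    p <- scene$params[[i]]
    if (p$class == "PHAS") p$mean_reads_per_library
    else p$expression_rpm * depth / 1e6
  }, numeric(1))
  if (sum(expected) > depth) {
    stop("locus expression exceeds library depth")
  }
  glen <- unname(scene$seqlengths[scene$chrom])
  with_seed(seed, {
    if (expression_noise_sdlog > 0) {
      noise <- rlnorm(length(expected), -expression_noise_sdlog^2 / 2,
                      expression_noise_sdlog)
      expected <- expected * noise
    }
    counts <- as.vector(rmultinom(1, round(sum(expected)), expected))
    parts <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      n <- counts[i]
      if (n == 0) next
      p <- scene$params[[i]]
      parts[[i]] <- if (p$class == "PHAS") {
        emit_phas(p, truth[i, ], scene$weights[[i]], n)
      } else {
        emit_hc(p, truth[i, ], scene$weights[[i]], n)
      }
    }
    reads <- do.call(rbind, parts)
    reads$start <- pmax(0L, pmin(reads$start, glen - reads$length))
    srna_library(reads, library_id = library_id, total_primary = depth)
  })
}

emit_phas <- function(p, row, W, n) {
  s <- p$phase_size
  n_bg <- rbinom(1, n, p$offphase_fraction %||% 0)
  bg <- NULL
  if (n_bg > 0) {
    n <- n - n_bg
    width <- row$end - row$start
    bg <- data.frame(
      chrom = row$chrom,
      start = as.integer(row$start + floor(runif(n_bg) * max(1, width - s))),
      length = s, strand = sample(c("+", "-"), n_bg, replace = TRUE),
      count = 1, n_placements = 1L, stringsAsFactors = FALSE)
    if (n == 0) return(bg)
  }
  slots <- sample.int(2 * p$n_cycles, n, replace = TRUE, prob = as.vector(W))
  strand_minus <- (slots - 1) %% 2 == 1      # W rows: 1 = plus, 2 = minus
  cyc <- (slots - 1) %/% 2
  coord <- row$trigger + cyc * s
  inreg <- runif(n) < p$precision
  shift <- integer(n)
  off <- !inreg
  if (any(off)) {
    mag <- sample.int(p$jitter, sum(off), replace = TRUE)
    shift[off] <- mag * sample(c(-1L, 1L), sum(off), replace = TRUE)
  }
  start <- ifelse(strand_minus, coord - 2L, coord) + shift
  out <- data.frame(chrom = row$chrom, start = as.integer(start), length = s,
                    strand = ifelse(strand_minus, "-", "+"), count = 1,
                    n_placements = 1L, stringsAsFactors = FALSE)
  if (is.null(bg)) out else rbind(out, bg)
}

emit_hc <- function(p, row, W, n) {
  if (p$placement == "uniform") {
    # fresh i.i.d. positions per library: the exchangeable null
    lens <- as.integer(sample(names(p$size_distribution), n, replace = TRUE,
                              prob = p$size_distribution))
    rel <- floor(runif(n) * pmax(1, p$length - lens + 1))
    multi <- runif(n) < p$multimap_fraction
    np <- rep(1L, n)
    if (any(multi)) np[multi] <- sample(2:5, sum(multi), replace = TRUE)
    return(data.frame(chrom = row$chrom, start = as.integer(row$start + rel),
                      length = lens,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      count = 1, n_placements = np, stringsAsFactors = FALSE))
  }
  # clustered: multinomial resampling of the locus's fixed read catalogue
  cnt <- as.vector(rmultinom(1, n, W$w))
  keep <- cnt > 0
  data.frame(chrom = row$chrom, start = as.integer(row$start + W$rel[keep]),
             length = W$length[keep], strand = W$strand[keep],
             count = cnt[keep], n_placements = W$n_placements[keep],
             stringsAsFactors = FALSE)
}

#' Build the false-positive scenario grid
#'
#' An all-hc-siRNA scene spanning a grid of locus lengths and expression
#' levels, plus a set of true PHAS positive controls for cutoff calibration,
#' resampled in several independent libraries. This is the experiment that
#' probes how locus length and expression drive spurious consensus PHAS
#' calls.
#'
#' @param lengths hc locus lengths in nt.
#' @param expressions hc locus expressions in RPM.
#' @param n_per_cell hc loci per (length, expression) cell.
#' @param n_libraries number of independent libraries.
#' @param seed master seed (scene and library seeds derive from it).
#' @param depth primary alignments per library.
#' @param n_controls number of PHAS positive-control loci. Control
#'   expression is heterogeneous: per-locus mean reads per library are
#'   log-normal (median `control_median_reads`, sdlog
#'   `control_reads_sdlog`, floored at `control_floor_reads`), emulating
#'   the order-of-magnitude expression spread among real known PHAS loci
#'   while keeping every control evaluable in every library.
#' @param control_params [phas_params()] template shared by the controls
#'   (phase size, cycles, precision, jitter, off-phase background).
#' @param control_median_reads median control reads per library.
#' @param control_reads_sdlog log-sd of control reads per library.
#' @param control_floor_reads minimum mean control reads per library.
#' @param placement hc placement model.
#' @return list with `scene`, `libraries` (list of `srna_library`), `truth`
#'   (with `cell`, `cell_length`, `cell_rpm` for hc loci), `control_ids`,
#'   `hc_ids`.
#' @export
scenario_grid <- function(lengths = c(500, 2000, 10000),
                          expressions = c(1, 100, 1000),
                          n_per_cell = 100, n_libraries = 8, seed = 1,
                          depth = 1e7, n_controls = 50,
                          control_params = phas_params(offphase_fraction = 0.3),
                          control_median_reads = 30,
                          control_reads_sdlog = 0.6,
                          control_floor_reads = 15,
                          placement = "clustered") {
  cells <- expand.grid(length = lengths, rpm = expressions)
  loci <- list()
  cell_lab <- character(0)
  for (ci in seq_len(nrow(cells))) {
    for (j in seq_len(n_per_cell)) {
      loci[[length(loci) + 1L]] <- hc_params(
        length = cells$length[ci], expression_rpm = cells$rpm[ci],
        placement = placement)
      cell_lab <- c(cell_lab, sprintf("%dnt_%grpm", cells$length[ci],
                                      cells$rpm[ci]))
    }
  }
  n_hc <- length(loci)
  seeds <- child_seeds(seed, n_libraries + 2)
  control_means <- with_seed(seeds[n_libraries + 2], {
    pmax(control_floor_reads,
         rlnorm(n_controls, log(control_median_reads), control_reads_sdlog))
  })
  for (j in seq_len(n_controls)) {
    p <- control_params
    p$mean_reads_per_library <- control_means[j]
    loci[[length(loci) + 1L]] <- p
    cell_lab <- c(cell_lab, "control")
  }
  need <- sum(vapply(loci, function(p) {
    if (p$class == "PHAS") p$n_cycles * p$phase_size + 2 * (2 + p$jitter)
    else p$length
  }, numeric(1)))
  gap <- 200
  genome_length <- ceiling(need + gap * (length(loci) + 1) + 10000)
  scene <- simulate_scene(loci, genome_length, seed = seeds[1],
                          emit_sequence = FALSE, gap = gap)
  truth <- scene$truth
  truth$cell <- cell_lab
  truth$cell_length <- c(rep(cells$length, each = n_per_cell)[seq_len(n_hc)],
                         rep(NA, n_controls))
  truth$cell_rpm <- c(rep(cells$rpm, each = n_per_cell)[seq_len(n_hc)],
                      rep(NA, n_controls))
  libraries <- lapply(seq_len(n_libraries), function(j) {
    sample_library(scene, library_id = sprintf("lib%d", j), depth = depth,
                   seed = seeds[j + 1])
  })
  list(scene = scene, libraries = libraries, truth = truth,
       control_ids = truth$locus_id[truth$cell == "control"],
       hc_ids = truth$locus_id[truth$cell != "control"])
}
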