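---
title: "Screening for PHAS loci and diagnosing heterochromatic false positives"
author: "phascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for PHAS loci and diagnosing heterochromatic false positives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phascreen)
```

## The problem

Phased secondary siRNAs (phasiRNAs) are produced in fixed s-nt increments
(s = 21 or 24) downstream of a defined small-RNA-guided cleavage site on a
precursor transcript. A genomic locus producing them — a *PHAS* locus — is
recognizable in sRNA-seq data because read 5′ ends fall predominantly into
one residue class mod s, the *phase register*. Plant genomes, however, are
full of heterochromatic siRNA (hc-siRNA) loci: imprecisely processed,
24-nt-dominated, transposon-associated loci that are both numerous and often
highly expressed. When phasing statistics are scanned across all
24-nt-dominated loci, some hc-siRNA loci pass — not because they are phased,
but because sheer read abundance makes locally "in-phase-looking"
configurations inevitable. `phascreen` implements both halves of the
problem: the screen (three phasing detectors, calibrated cutoffs,
multi-library consensus) and the post-hoc diagnostics that expose the
survivors as false positives.

## Register arithmetic

All coordinates are 0-based half-open. A plus-strand read's register is
`start mod s`. A minus-strand read's register is `(end + 2) mod s`: the +2
encodes the 2-nt 3′ overhang left by Dicer processing, so both strands of a
perfect duplex share one register. Equivalently, every read maps to a
strand-collapsed *phase coordinate* (`start` for +, `end + 2 − s` for −);
duplex partners share the coordinate exactly. This invariance is tested
exhaustively over a full phase period for both s = 21 and s = 24.

## The three detectors

Each detector scans windows of m phase cycles (m·s nt), stepped one cycle at
a time and anchored at the locus start, so all three statistics are
invariant under translating a locus by any multiple of s. Loci shorter than
m cycles are evaluated as a single full-span window. Only reads of exactly
length s enter an s-nt analysis by default (`length_tolerance` widens this).

* **Log-odds score** (`phase_logodds`, default m = 9). With P the in-phase
  abundance, U the out-of-phase abundance and k the number of occupied
  in-phase positions in the window, the score is
  `ln[(1 + 10·P/(1 + U))^(k−2)]` for k ≥ 3 and 0 otherwise. Reads 1 nt off
  register count toward P at weight 0.5 (and not toward U); positions in
  that ±1 drift band count toward k. The maximum over windows and candidate
  registers is reported.
* **Hypergeometric p-value** (`phase_hypergeom`, default m = 10). The window
  holds N = m·s strand-collapsed positions, K = m of which are in-register
  for a candidate register. With n distinct occupied positions of which x
  are in-register, the p-value is the upper tail P(X ≥ x) of the
  hypergeometric distribution. The minimum over windows and registers is
  reported. Within a window N, K and n are fixed, so the minimizing register
  is simply the one with the most occupied in-register slots — a shortcut
  the implementation exploits. **No multiple-testing correction is applied**
  across windows or loci: the three detectors are meant to be compared on
  equal footing, and two of them produce scores that cannot be adjusted.
  Callers who want a corrected p can apply `p.adjust` across loci afterward.
* **Phased-ratio score** (`phase_ratio`, default m = 9):
  `(P/(P+U))·k` with exact registers and no drift tolerance; 0 for an empty
  window.

The three formulas follow the detector families commonly used for PHAS
annotation (a ShortStack-style log-odds score, a hypergeometric tail on
occupied positions, and a phased-fraction score); each sits behind its own
function so variants can be swapped without touching the screen.

Ties — in dominant register, dominant read length, or maximizing register —
break toward the smallest index/length and are flagged where surfaced.

## Calibration and the consensus screen

`calibrate_cutoffs` turns phasing results for positive-control loci into
pass cutoffs. Two details matter:

* **Per-locus aggregation.** A control "passes the screen" only if it passes
  in *every* library, so each control locus is first summarized by its
  weakest library (minimum score, maximum p-value) and the calibration
  quantile is taken over those summaries. Calibrating on pooled
  locus-by-library cells (available via `per_locus = FALSE`) passes ~95% of
  *cells* but much less than 95% of *loci*.
* **Type-6 quantiles.** The `quantile`-th percentile uses the type-6
  interpolation rule (h = (n+1)p), whose coverage is unbiased: the expected
  fraction of new control-like loci falling below the cutoff equals the
  quantile. The default type-7 rule is biased low as a tail estimator (at
  n = 50 and p = 0.05 it tracks the ~3.45th order statistic, i.e. ~6.8%
  expected coverage).

The p-value cutoff is the (1 − quantile) percentile of control p-values,
capped at 0.05. Score cutoffs can legitimately calibrate to 0 when a weak
control is nearly empty in its worst library; a 0 cutoff means that detector
rejects only no-data cells, which mirrors how permissive individual
detectors are in practice — the stringency of the screen comes from the
consensus, not from any single detector.

`screen_loci` evaluates every locus with all three detectors in every
library. A locus with no eligible reads in a library fails all three cells
there (recorded as no-data): consensus means *consistently phased in all
libraries*, and absence of data is not evidence of phasing. The consensus
flag requires all 3 × L cells; Venn tallies count loci passing each detector
subset in all libraries. Tightening any cutoff can only shrink the consensus
set (tested).

## Diagnostics

`diagnose_screen` applies the checks that separate genuine PHAS loci from
highly expressed hc-siRNA survivors:

* **Register consistency** — the same dominant register in every library
  with data. A genuine PHAS locus has a locus-intrinsic trigger site; its
  dominant register cannot change between libraries.
* **Majority criterion** — dominant register fraction > 0.5 in every
  library. Genuine loci keep a majority of reads in one register even with
  off-phase background; hc-siRNA loci spread abundance over many registers.
* Locus properties — length, RPM, abundance-weighted multimapping fraction,
  feature-class overlap (TE priority over gene, because TE overlap is the
  hc-siRNA signature; the priority is an argument).

The verdict is `PHAS-supported` only when register consistency and the
majority criterion both hold. The raw consensus is deliberately exposed
separately from the verdict so that consensus false positives can be studied
rather than silently suppressed.

## The synthetic data generator

`simulate_scene`/`sample_library` generate ground-truthed scenes two locus
classes at a time:

* **PHAS loci** (`phas_params`): reads at `trigger + i·s` on both strands
  with duplex geometry; each read is exactly in register with probability
  `precision` (default 0.95), else its 5′ end shifts by ±1..`jitter`
  (default 3) nt. Per-position abundance weights are log-normal and drawn
  once per scene, so independent libraries resample the same hotspots, as
  real libraries do. `offphase_fraction` (default 0) adds uniform off-phase
  background — degradation fragments and transitive spreading give real PHAS
  loci a *majority*, not a purity, of in-register reads.
* **hc-siRNA loci** (`hc_params`): 24-nt-dominated reads (80% mass at 24 nt
  by default) over loci of tunable length and RPM. Under `uniform` placement
  5′ positions are i.i.d. uniform per library — the exchangeable null under
  which the register histogram is asymptotically uniform (verified by
  chi-square at n ≈ 10^5). Under `clustered` placement the locus owns a
  fixed catalogue of read species (one per ~15 nt by default, island
  clustered, log-normal abundances spanning several orders of magnitude)
  that every library resamples multinomially. The catalogue reflects
  hc-siRNA biology — short Pol IV precursors have defined termini, so the
  same 5′ positions recur across libraries — and it is precisely this
  recurrence that lets an unphased locus pass a consensus screen: a
  chance in-register configuration of heavy species persists in every
  library.

Libraries default to 10^7 primary alignments (a typical mapped sRNA-seq
library) and apply per-locus log-normal expression noise between libraries
(sdlog 0.4), as biological replicates do. Everything is deterministic given
the seed; identical (configuration, seed) pairs give byte-identical output.

What the generator does **not** emulate: nucleotide-composition biases,
ligation bias, the erroneous placement of multimapping reads (multimapping
is flagged but placements are taken as given, matching the pipeline's
treatment of real alignments), 21/22-nt mixed PHAS registers, and genome
repeat structure. Passing tests therefore demonstrate the statistical logic
of the screen, not robustness to alignment artifacts.

## Bundled experiments and their problem sizes

Two experiments, run both by the test suite and by `scripts/acceptance.R`,
characterize the screen:

* **Sensitivity.** Cutoffs are calibrated at quantile 0.05 on 50 simulated
  positive controls shaped like a curated set of known PHAS loci: per-locus
  mean reads log-normal (median 30/library, sdlog 0.6, floored at 15 so
  every control is evaluable in every library), precision 0.95, 30%
  off-phase background. The screen is then applied to 200 held-out PHAS loci
  (median 60 reads, floor 30, precision 0.95, no background) in 4 libraries.
  Consensus recovery and register-consistency rates are reported.
* **False-positive grid** (`scenario_grid`). 100 clustered hc loci in each
  cell of {500, 2000, 10000} nt × {1, 100, 1000} RPM, plus the same control
  cohort, sampled in 8 libraries. The consensus false-positive rate per cell,
  its gradient along length × expression (Spearman), and the fraction of
  consensus false positives flagged `not-PHAS-supported` by the register
  diagnostics are reported. The qualitative result — false positives
  concentrate among long, highly expressed loci, and register diagnostics
  flag them — is the package's central reproduction target.

The enumeration oracle for the hypergeometric tail runs exhaustively (all
subsets, all K) for N ≤ 14 and over sparse and near-saturated occupancies
for window-sized N ∈ {21, 24}; the homolog scanner is checked against a
position-by-position Hamming oracle on a 100-kb genome; the null behavior of
register consistency is estimated from 1,000 uniform-random replicates.
These sizes keep the whole suite within a few minutes on one CPU while
covering the regimes the statistics actually visit.

## Homology and targeting

`scan_homologs` reports every genomic window on either strand within a
Hamming distance of `max_mm` (default 2) of a mature miRNA query — matching
an aligner run with a mismatch allowance and no indels. `extract_context`
returns hit ± 200 nt, reverse-complemented for minus-strand hits.
`hairpin_check` replaces visual inspection of folds with an explicit rule:
the best gap-free antiparallel duplex between the mature span and any
non-overlapping context window (loop ≥ 3 nt) must leave at most 5 unpaired
mature positions and no run of more than 3; G:U wobbles count as paired. An
optional `folder` hook (e.g. `rnafold_folder()`) delegates the structure to
an external thermodynamic folder, from which the same duplex criteria are
read. `allen_score` implements position-weighted target penalties (0 per
Watson-Crick pair, 0.5 per G:U, 1 per mismatch, doubled at positions 2–13)
under a gap-free antiparallel model; `predict_targets` scans all windows and
keeps alignments at or below the conventional cutoff of 3.

## Known limitations

* The three detector formulas are concrete defaults for their families;
  published tools differ in details (window stepping, drift handling,
  abundance weighting), so absolute score values are not comparable across
  tools — only the screen's logic is.
* The hypergeometric position model collapses strands via the duplex rule;
  methods that count strands separately will give different (usually
  smaller) p-values at the same configuration.
* Multimapping reads are used where the input places them; the
  multimapping fraction is reported as a diagnostic only.
* The hairpin rule is a screen, not a substitute for thermodynamic folding;
  borderline precursors should be folded externally via the hook.
* Cutoffs calibrated from very weak control sets can degenerate (score 0 /
  p 0.05); inspect the `provenance` and the control score distributions
  before trusting a screen.
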