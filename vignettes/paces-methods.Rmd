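---
title: "Motif-level prediction of mRNA ac4C acetylation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-level prediction of mRNA ac4C acetylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paces)
```

## The problem and the unit of prediction

N4-acetylcytidine (ac4C) in mRNA is mapped experimentally by acRIP-seq,
which yields enrichment peaks of roughly 100–300 nt — far coarser than a
single modified cytidine. Within those peaks, repeating CXX motifs (an
obligate C every third position) are strongly over-represented. `paces`
therefore predicts at the *motif* level: the candidate unit is a run of at
least five consecutive CXX repeats, represented by the 15-nt span of five
repeats plus symmetric flanking sequence. It does not, and cannot, point
at the exact acetylated cytidine; that limitation is inherited from the
resolution of the experimental data the approach is modeled on.

## Scanning and coordinates

`scanCxxMotifs()` reports every maximal run of phase-aligned cytidines
with at least `minRepeats` (default 5) repeats. The two X positions are
unconstrained — including C and N — so a poly-C stretch legitimately
contains up to three phase-offset runs; each phase is scanned and
maximality judged independently. A repeat is only counted when its full
CXX triplet lies inside the sequence, so every reported site spans
exactly `3 * repeatCount` nt; a trailing obligate C whose two X positions
would fall off the transcript does not count as a repeat, and
symmetrically it does not break maximality of the run to its left.

All ranges and user-facing coordinates are 1-based inclusive, the
GenomicRanges convention; the peak-table TSV on disk is 0-based
half-open (the common peak-caller convention) and converted on read.
Only the sense strand is scanned: the target is mRNA.

Windows that run past a transcript end are N-padded rather than dropped,
so motifs on short transcripts remain predictable; the padded positions
are recorded per sample and contribute nothing to any encoding (tokens
containing N are never counted, and positional encodings map them to 0).

## Dataset construction

Runs fully inside an annotated peak are positive candidates; each peak
contributes at most one positive — among all 5-repeat sub-windows of the
runs it contains, the one whose midpoint is nearest the peak summit, with
ties broken toward the smaller start coordinate. Runs touching no peak
are negatives, trimmed to their first five repeats so that one maximal
run yields one negative rather than a fan of near-duplicates. Runs that
straddle a peak edge have an ambiguous label and are discarded entirely.
These three conventions (midpoint distance, first-five trimming,
straddle exclusion) are choices this package fixes and documents; the
labeling idea itself — inside peaks positive, outside negative, nearest
the summit when a peak holds several motifs — follows the acRIP-seq
setting this design targets. With peak data at the published scale the
class ratio lands near 1:10; the train/test split is stratified random
with a mandatory recorded seed (the published partition of 1160/10855
training versus 469/4343 test samples was, by its own arithmetic, not
exactly class-proportional, so a proportional stratified split
reproduces its positive counts exactly and its negative counts to within
about 30).

## Encodings

Five encodings are implemented; the final predictor uses two of them.

* **One-hot** (window 126): C, G, T, A become the unit vectors
  (1,0,0,0) … (0,0,0,1); N is all-zero.
* **PSNSP / PSDSP** (windows 144 / 138): position-specific profiles
  `f(i, n) = N+(i, n)/Np − N−(i, n)/Nn`, the per-position difference in
  token frequency between classes, with tokens the 4 nucleotides or the
  16 overlapping dinucleotides. Values lie in [−1, 1]; swapping the
  classes negates the table. Profiles are fitted on training data only
  and frozen before any validation or test sample is encoded — inside
  cross-validation they are refitted per fold on the fold-training part,
  a leakage guard that costs a little optimism but keeps out-of-fold
  scores honest.
* **KNF** (window 150): frequencies of all 2-, 3-, 4-mers
  (16 + 64 + 256 = 336 features). Each k-block is normalized by its own
  number of N-free windows, making the block a probability simplex; this
  fixes the denominator that "occurrence frequency" leaves open, and the
  sum-to-one property is asserted in the tests.
* **KSNPF** (window 144): frequencies of ordered nucleotide pairs
  separated by k = 0..4 arbitrary residues (16 × 5 = 80 features),
  normalized per spacing the same way.

K-mers and pairs are ordered lexicographically (A < C < G < T)
throughout. Ordering is irrelevant to forest training but is part of the
serialized feature layout, so it is fixed and documented. The window
sizes above are the cross-validation-tuned values used as defaults; the
total flank W is split half per side, consistent with the even,
6-divisible tuning grid (0–198).

## Forests, combination, calibration

Each encoding feeds a probability random forest (`ranger`,
single-threaded, seeded, 800 trees by default — the tuned tree count;
other hyperparameters stay at package defaults, which make little
difference here and are recorded inside the fitted object). The
meta-classifier is the weighted sum of the PSDSP and KNF forest
probabilities. The original work never published its ensemble weights,
so the default here is the balanced (0.5, 0.5) pair — reproducibility
over tuning — with an optional grid search (step 0.1) over
cross-validated out-of-fold scores; exact ties break toward balance.

Specificity thresholds are calibrated on the out-of-fold *negative*
training scores, never on test data: `threshold(q)` is the smallest
observed score with at least a fraction q of negatives strictly below it
(a conservative empirical quantile; if no observed score qualifies, a
value just above the maximum is returned with a warning). Thresholds are
monotone across the 99/95/90/85 % settings by construction, and the
call set at a lower specificity is always a superset of the call set at
a higher one.

At prediction time every 5-repeat window of a maximal run is scored and
the best window represents the run (ties to the smaller start); this
mirrors the overlapping-motif resolution of the public server. The local
CLI reports all runs with a boolean call column (`--calls-only` restores
the server's suppression behavior) and warns, rather than errors, above
the server's 50-sequence batch size.

## Evaluation

ROC and precision-recall curves come from a grouped-threshold sweep over
the distinct scores; the trapezoid auROC is then exactly the normalized
Mann–Whitney U statistic with half credit for ties (asserted against a
pair-counting oracle in the tests). Cross-validation reports pool the
out-of-fold scores of all folds into a single curve rather than
averaging per-fold areas. The break-even point is found by linear
interpolation between the two PR points straddling precision = recall;
the PR curve is anchored at the swept endpoints with a constant-precision
step to recall 0, and no optimistic interpolation toward (0, 1).

## The synthetic benchmark

`simulateAcetylationData()` emulates the acRIP-seq setting at a 1:10
class ratio: each transcript carries one positive motif at the centre of
a fixed 201-nt peak (summit at the centre) and a share of the negative
motifs in 200-nt slots well away from the peak. Two independent,
strength-tunable signal channels distinguish the classes, chosen to echo
the feature classes the two encoders consume: positive flanks are drawn
with G probability `0.25 + γ · 0.2` (a composition signal for KNF), and
with probability γ the dinucleotide immediately upstream of the positive
motif is set to GG (a positional signal for PSDSP). Repeat counts are
drawn from a distribution over 5–9 (0.6/0.2/0.1/0.06/0.04 — most
real runs are short); X positions come from the class's flank
distribution; everything else is i.i.d. uniform ACGT.

Two geometric precautions keep γ = 0 a genuine null: negative slots are
wide enough (200 nt) that no encoder window reaches a neighbouring
planted motif, and the positive run is anchored so that its *first*
5-repeat window is the summit-nearest one — the same window the negative
labeling convention keeps — so trimming geometry is identical across
classes. Both were found the hard way: with narrower slots or a centred
run, a positional classifier reads the layout instead of the signal and
the null sits near auROC 0.8. Accidental CXX runs arising in random
flanks are removed by point mutation so that scanning recovers exactly
the planted ground truth.

What the generator does *not* emulate: real transcript base composition
(background is uniform), peak-width variation, multiple peaks per
transcript, coverage noise, or any sequence determinant of acetylation
beyond the two planted channels. Passing the signal-recovery suite
therefore shows the pipeline can learn composition and positional flank
signal at realistic class imbalance — not that it attains any particular
accuracy on real acRIP-seq data, whose published headline numbers
(cross-validation auROC 0.8674 for PSDSP alone, 0.8851 combined with
KNF, 0.8741 on independent test) additionally depend on the original
dataset and unpublished ensemble weights.

## Problem sizes and numerical choices

The test suite and the acceptance script run the signal-recovery
benchmark at 500 positives / 5000 negatives with 200-tree forests — the
package's fast verification profile; 800 trees is the analysis default.
Null-signal auROC is averaged over three seeds because a single held-out
evaluation at this size has a sampling spread of a few hundredths.
Exhaustive scanner verification runs over all C-placement patterns up to
length 12 (the {A, C} strings cover every equivalence class, since
scanning depends only on which positions carry C) plus 1000 random
200-nt sequences against a brute-force oracle.

Degenerate inputs are handled explicitly: empty sequences scan to empty
results; single-class training sets, unknown peak sequence ids, odd
window sizes and out-of-range generator parameters are hard errors; an
all-equal negative score distribution yields above-maximum thresholds
with a warning. Every stochastic step (splits, folds, forests,
simulation) takes a required or defaulted integer seed and restores the
caller's RNG state.
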