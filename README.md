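# paces

Prediction of N4-acetylcytidine (ac4C) modification motifs in human mRNA.

ac4C is the only acetylation event described in eukaryotic mRNA; it is
enriched in coding sequence and marks transcripts for increased stability
and translation. Antibody-based sequencing (acRIP-seq) locates it only to
100–300 nt peaks, within which runs of repeating **CXX motifs** — an
obligate cytidine every third position, `CXXCXXCXXCXXC..` — are strongly
over-represented. `paces` predicts, at motif level, which runs of at least
five CXX repeats are likely acetylation contexts, for anyone mining
transcript sequences for candidate ac4C sites.

## Method

A candidate is the 15-nt span of five consecutive CXX repeats plus `W/2`
nt of flank on each side. Two feature encodings feed two random forests:

- **PSDSP** (position-specific dinucleotide sequence profile, `W = 138`):
  each overlapping dinucleotide at position *i* is replaced by

  `f(i, n) = N+(i, n) / Np − N−(i, n) / Nn`

  the difference between the fraction of positive and negative training
  samples carrying dinucleotide *n* at position *i*.
- **KNF** (k-nucleotide frequencies, `W = 150`): the 336 overlapping
  2-, 3- and 4-mer frequencies of the window (16 + 64 + 256).

The meta-classifier is the weighted sum of the two forest probabilities
(balanced weights by default, optional cross-validated grid tuning).
Score thresholds are calibrated on out-of-fold negative training scores
so that a chosen fraction — 99, 95, 90 or 85 % — of negatives falls below
the threshold; prediction reports every maximal CXX run with the score of
its best 5-repeat window and a call against the chosen specificity.

One-hot, PSNSP (single-nucleotide profile) and KSNPF (k-spaced nucleotide
pair) encodings are also implemented for encoder comparison via
`crossValidate()`.

Labeled datasets are built from transcript FASTA plus a peak table: runs
fully inside a peak yield one positive per peak (the 5-repeat window
nearest the summit), runs outside all peaks are negatives, straddling
runs are discarded. A synthetic acRIP-seq-like generator
(`simulateAcetylationData()`) plants a G-rich flank composition and a
motif-proximal dinucleotide with tunable strength, so the whole pipeline
is benchmarkable without external data.

## Worked example

```r
library(paces)

sim <- simulateAcetylationData(nPeaks = 100, nBackgroundMotifs = 1000,
                               signalStrength = 1, seed = 3)
ds  <- buildDataset(sim$sequences, sim$peaks)
sp  <- splitTrainTest(ds, testFraction = 0.3, seed = 3)
model <- pacesTrain(sp$train, nTrees = 200, seed = 3)
model
#> PacesModel: PSDSP + KNF random-forest meta-classifier
#>   windows: PSDSP 138, KNF 150; trees: 200; seed: 3
#>   weights: psdsp 0.50, knf 0.50
#>   specificity thresholds:
#>     99% -> 0.1653
#>     95% -> 0.1008
#>     90% -> 0.0745
#>     85% -> 0.0646

computeMetrics(pacesScore(model, sp$test), sampleLabels(sp$test))
#> EvaluationReport: 30 positives vs 300 negatives
#>   auROC = 1.0000  auPRC = 1.0000  BEP = 1.0000

head(pacesPredict(model, sim$sequences[1], specificity = 0.9), 3)
#>   seq_id start end repeat_count      score specificity  threshold call
#> 1 tx0001    40  54            9 0.20239286         0.9 0.07450198 TRUE
#> 2 tx0001   146 160            7 0.18324603         0.9 0.07450198 TRUE
#> 3 tx0001   243 257            5 0.01148810         0.9 0.07450198 FALSE
```

The thresholds are the calibrated score cutoffs per nominal specificity
(on this strong-signal simulation nearly all planted positives score far
above them). Each prediction row is one maximal CXX run: 1-based
inclusive coordinates of its best-scoring 5-repeat window, the meta
score, and the call at the requested specificity.

A command-line front end over the same functions is installed at
`inst/scripts/paces.R` (subcommands `scan`, `simulate`, `build-dataset`,
`train`, `cv`, `predict`).

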