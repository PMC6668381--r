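Package: paces
Title: Prediction of N4-Acetylcytidine (ac4C) Modification Motifs in mRNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans mRNA/cDNA sequences for repeating CXX motifs (runs of
    obligate cytidines spaced by two arbitrary nucleotides), encodes fixed
    windows around them with position-specific (di)nucleotide sequence
    profiles and k-nucleotide composition features, trains random-forest
    classifiers on acRIP-seq-derived positive/negative motif sets, combines
    the position-specific dinucleotide profile and k-nucleotide frequency
    classifiers into a weighted meta-classifier, calibrates specificity
    thresholds, and scores candidate acetylation motifs in query sequences.
    Includes a synthetic-data generator with plantable flanking-composition
    signal for benchmarking the full pipeline without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: Classification, Epitranscriptomics, MotifDiscovery, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
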