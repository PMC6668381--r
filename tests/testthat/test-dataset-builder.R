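test_that("peak containment drives the positive/negative labeling", {
    # one motif inside the peak, one outside
    ch <- rep("A", 60)
    ch[10 + 3 * (0:4)] <- "C"    # run at 10..24 (inside peak 5..30)
    ch[40 + 3 * (0:4)] <- "C"    # run at 40..54 (outside)
    seqs <- c(t1 = paste(ch, collapse = ""))
    ds <- buildDataset(seqs, grPeak("t1", 5, 30, 15), window = 0)
    expect_equal(positiveCount(ds), 1L)
    expect_equal(negativeCount(ds), 1L)
    expect_equal(sampleMotifStart(ds)[sampleLabels(ds) == "positive"], 10L)
    expect_equal(sampleMotifStart(ds)[sampleLabels(ds) == "negative"], 40L)
})

test_that("among in-peak motifs the one nearest the summit wins", {
    ch <- rep("A", 100)
    ch[11 + 3 * (0:4)] <- "C"    # midpoint 18
    ch[61 + 3 * (0:4)] <- "C"    # midpoint 68
    seqs <- c(t1 = paste(ch, collapse = ""))
    dsA <- buildDataset(seqs, grPeak("t1", 1, 90, 25), window = 0)
    expect_equal(sampleMotifStart(dsA)[sampleLabels(dsA) == "positive"], 11L)
    dsB <- buildDataset(seqs, grPeak("t1", 1, 90, 70), window = 0)
    expect_equal(sampleMotifStart(dsB)[sampleLabels(dsB) == "positive"], 61L)
})

test_that("motifs straddling a peak boundary are discarded from both classes", {
    ch <- rep("A", 80)
    ch[20 + 3 * (0:4)] <- "C"    # run 20..34, peak ends at 27: straddles
    seqs <- c(t1 = paste(ch, collapse = ""))
    ds <- buildDataset(seqs, grPeak("t1", 5, 27, 15), window = 0)
    expect_equal(length(ds), 0L)
})

test_that("peaks naming unknown sequences are a hard error", {
    seqs <- c(t1 = plantMotif(40, 5, 5))
    expect_error(buildDataset(seqs, grPeak("ghost", 1, 30, 10)), "ghost")
})

test_that("labeling agrees with a brute-force containment oracle on synthetic data", {
    sim <- simulateAcetylationData(nPeaks = 200, nBackgroundMotifs = 2000,
                                   signalStrength = 0.5, seed = 77)
    ds <- buildDataset(sim$sequences, sim$peaks, window = 0)
    expect_equal(positiveCount(ds), 200L)
    expect_equal(negativeCount(ds), 2000L)

    # oracle: label every truth motif by plain interval arithmetic
    pk <- data.frame(id = as.character(GenomicRanges::seqnames(sim$peaks)),
                     from = GenomicRanges::start(sim$peaks),
                     to = GenomicRanges::end(sim$peaks))
    tr <- sim$truth
    oracle <- vapply(seq_len(nrow(tr)), function(i) {
        lo <- tr$start[i]; hi <- tr$start[i] + 3 * tr$repeat_count[i] - 1
        p <- pk[pk$id == tr$seq_id[i], ]
        if (any(lo >= p$from & hi <= p$to)) "positive"
        else if (any(lo <= p$to & hi >= p$from)) "ambiguous"
        else "negative"
    }, character(1))
    expect_equal(sum(oracle == "positive"), positiveCount(ds))
    expect_equal(sum(oracle == "negative"), negativeCount(ds))
    # the dataset's negatives are exactly the oracle's negative motifs
    negKey <- paste(sampleSeqId(ds), sampleMotifStart(ds))[
        sampleLabels(ds) == "negative"]
    oracleKey <- paste(tr$seq_id, tr$start)[oracle == "negative"]
    expect_setequal(negKey, oracleKey)
})

test_that("train/test split is stratified, disjoint, exhaustive and seeded", {
    ds <- makeRatioFixture(nPos = 163, nNeg = 1520, seed = 5)
    sp1 <- splitTrainTest(ds, 0.288, seed = 9)
    sp2 <- splitTrainTest(ds, 0.288, seed = 9)
    expect_identical(sampleSeqId(sp1$test), sampleSeqId(sp2$test))

    idTr <- sampleSeqId(sp1$train); idTe <- sampleSeqId(sp1$test)
    expect_length(intersect(idTr, idTe), 0L)
    expect_setequal(c(idTr, idTe), sampleSeqId(ds))

    # class ratio preserved to within a percentage point
    frTr <- positiveCount(sp1$train) / length(sp1$train)
    frTe <- positiveCount(sp1$test) / length(sp1$test)
    fr <- positiveCount(ds) / length(ds)
    expect_lt(abs(frTr - fr), 0.01)
    expect_lt(abs(frTe - fr), 0.01)

    tiny <- makeRatioFixture(nPos = 5, nNeg = 50, seed = 1)
    expect_error(splitTrainTest(tiny[c(1, 6:55)], 0.3, seed = 1),
                 "fewer than 2")
})

test_that("a full-size split reproduces the published partition shape", {
    ds <- makeRatioFixture(nPos = 1629, nNeg = 15198, seed = 2)
    sp <- splitTrainTest(ds, 469 / 1629, seed = 3)
    expect_equal(positiveCount(sp$test), 469L, tolerance = 0)
    expect_equal(positiveCount(sp$train), 1160L)
    # negatives follow the same fraction (proportional stratification)
    expect_equal(negativeCount(sp$test),
                 round(469 / 1629 * 15198), tolerance = 1)
})

test_that("peak tables round-trip through the TSV reader/writer", {
    pks <- grPeak(c("a", "b"), c(11, 101), c(60, 220), c(30, 150),
                  id = c("p1", "p2"))
    f <- tempfile(fileext = ".tsv")
    writePeakTable(pks, f)
    back <- readPeakTable(f)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(pks))
    expect_equal(GenomicRanges::end(back), GenomicRanges::end(pks))
    expect_equal(back$summit, pks$summit)
    expect_error(readPeakTable({
        g <- tempfile(); writeLines(
            "seq_id\tstart\tend\tsummit\na\t10\t5\t7", g); g
    }), "start < end")
})
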