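test_that("scanner finds constructed minimal runs and rejects motif-free input", {
    g <- scanCxxMotifs(c(tx = "CAACGGCTTCAGCTG"))
    expect_equal(length(g), 1L)
    expect_equal(GenomicRanges::start(g), 1L)
    expect_equal(GenomicRanges::width(g), 15L)
    expect_equal(g$repeatCount, 5L)

    expect_equal(length(scanCxxMotifs(c(tx = "AAAAAAAAAAAAAAA"))), 0L)
    expect_equal(length(scanCxxMotifs(c(tx = ""))), 0L)
})

test_that("scanner is invariant under case and U/T alphabet", {
    dna <- c(tx = "CAACGGCTTCAGCTG")
    rna <- c(tx = "caacggcuucagcug")
    expect_equal(scanAsFrame(unname(dna)), scanAsFrame(unname(rna)))
})

test_that("phase-offset runs in poly-C stretches are reported independently", {
    # CCCCCC...: each of the three phases carries its own maximal run
    s <- strrep("C", 21)
    g <- scanCxxMotifs(c(tx = s), minRepeats = 5L)
    starts <- GenomicRanges::start(g)
    expect_true(all(c(1L, 2L, 3L) %in% starts))
    expect_identical(scanAsFrame(s), bruteForceScan(s))
})

test_that("scanner matches brute force exhaustively over all C-patterns up to length 12", {
    # scanner output depends only on which positions carry C, so the
    # {A,C}^L strings cover every equivalence class of ACGT^L inputs
    for (L in 3:12) {
        combos <- expand.grid(rep(list(c("A", "C")), L),
                              stringsAsFactors = FALSE)
        strs <- do.call(paste0, combos)
        names(strs) <- sprintf("s%06d", seq_along(strs))
        g <- scanCxxMotifs(strs, minRepeats = 2L)
        bySeq <- split(data.frame(start = GenomicRanges::start(g),
                                  repeat_count = g$repeatCount),
                       factor(as.character(GenomicRanges::seqnames(g)),
                              levels = names(strs)))
        mismatch <- 0L
        for (i in seq_along(strs)) {
            got <- bySeq[[names(strs)[i]]]
            rownames(got) <- NULL
            if (!isTRUE(all.equal(got, bruteForceScan(strs[[i]], 2L))))
                mismatch <- mismatch + 1L
        }
        expect_equal(mismatch, 0L)
    }
})

test_that("scanner matches brute force on random full-alphabet strings", {
    set.seed(11)
    for (i in 1:200) {
        L <- sample(5:12, 1L)
        s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
        expect_identical(scanAsFrame(s, 2L), bruteForceScan(s, 2L))
    }
    for (i in 1:100) {
        s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
        expect_identical(scanAsFrame(s), bruteForceScan(s))
    }
})

test_that("reported runs are maximal in both directions", {
    set.seed(4)
    for (i in 1:50) {
        s <- paste(sample(c("A", "C", "G", "T"), 300,
                          replace = TRUE, prob = c(.2, .4, .2, .2)),
                   collapse = "")
        ch <- strsplit(s, "")[[1L]]
        g <- scanCxxMotifs(stats::setNames(s, "q"))
        for (j in seq_along(g)) {
            st <- GenomicRanges::start(g)[j]
            rc <- g$repeatCount[j]
            if (st - 3L >= 1L) expect_false(ch[st - 3L] == "C")
            rpos <- st + 3L * rc
            if (rpos + 2L <= nchar(s)) expect_false(ch[rpos] == "C")
        }
    }
})

test_that("candidate window enumeration yields repeat_count - 4 windows", {
    run7 <- scanCxxMotifs(c(tx = plantMotif(30, 2, 7)))
    expect_equal(run7$repeatCount, 7L)
    w <- enumerateCandidateWindows(run7)
    expect_equal(length(w), 3L)
    expect_equal(GenomicRanges::start(w), c(2L, 5L, 8L))
    expect_true(all(GenomicRanges::width(w) == 15L))

    run5 <- scanCxxMotifs(c(tx = plantMotif(20, 3, 5)))
    w5 <- enumerateCandidateWindows(run5)
    expect_equal(GenomicRanges::start(w5), GenomicRanges::start(run5))

    set.seed(2)
    for (rc in 5:9) {
        run <- scanCxxMotifs(c(tx = plantMotif(3 * rc + 10, 4, rc)))
        expect_equal(length(enumerateCandidateWindows(run)), rc - 4L)
    }
    run5$repeatCount <- 4L
    expect_error(enumerateCandidateWindows(run5), "repeatCount >= 5")
})

test_that("sample extraction pads symmetrically and always yields 15 + W nt", {
    seqs <- c(tx = "CAACGGCTTCAGCTG")
    site <- scanCxxMotifs(seqs)

    s0 <- extractSamples(seqs, site, window = 0)
    expect_equal(sampleResidues(s0), unname(seqs))
    expect_false(any(padMask(s0)))

    s6 <- extractSamples(seqs, site, window = 6)
    expect_equal(sampleResidues(s6), paste0("NNN", seqs[[1]], "NNN"))
    expect_equal(which(padMask(s6)[1L, ]), c(1:3, 19:21))

    expect_error(extractSamples(seqs, site, window = 5), "even")

    set.seed(9)
    long <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    sites <- scanCxxMotifs(stats::setNames(long, "t2"), minRepeats = 2L)
    sites <- sites[sites$repeatCount >= 5L]
    if (length(sites)) {
        smp <- extractSamples(stats::setNames(long, "t2"),
                              trimToFiveRepeats(sites), window = 138)
        expect_true(all(nchar(sampleResidues(smp)) == 153L))
    }
})

test_that("trimming samples to a narrower window preserves the motif core", {
    x <- randomSamples(20, window = 150, seed = 3)
    y <- trimSamples(x, 138)
    expect_equal(sampleWindow(y), 138L)
    expect_equal(substr(sampleResidues(y), 70, 84),
                 substr(sampleResidues(x), 76, 90))
    expect_error(trimSamples(x, 160), "widen")
    expect_error(trimSamples(x, 137), "even")
})
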