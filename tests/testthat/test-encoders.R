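test_that("one-hot follows the binary-vector mapping with N as all-zero", {
    v <- encodeOneHot("C")
    expect_equal(unname(v[1L, ]), c(1, 0, 0, 0))
    expect_equal(unname(encodeOneHot("G")[1L, ]), c(0, 1, 0, 0))
    expect_equal(unname(encodeOneHot("T")[1L, ]), c(0, 0, 1, 0))
    expect_equal(unname(encodeOneHot("A")[1L, ]), c(0, 0, 0, 1))
    expect_equal(unname(encodeOneHot("N")[1L, ]), c(0, 0, 0, 0))

    s <- randomSamples(4, window = 126, seed = 2)
    expect_equal(ncol(encodeOneHot(s)), 564L)   # 4 * (15 + 126)
})

test_that("position profiles reproduce hand-computed frequency differences", {
    p <- fitPositionProfile(c("ACG", "ACG", "ATG", "TCG", "ACG"),
                            order = 1, labels = c(1, 1, 1, 0, 0))
    tab <- profileTable(p)
    expect_equal(unname(tab[1, "A"]), 3 / 3 - 1 / 2)          # 0.5
    expect_equal(unname(tab[1, "T"]), 0 / 3 - 1 / 2)
    expect_equal(unname(tab[2, "C"]), 2 / 3 - 2 / 2)
    expect_equal(unname(tab[2, "T"]), 1 / 3 - 0 / 2)
    expect_equal(unname(tab[3, "G"]), 0)                      # all G in both classes

    enc <- encodePSNSP("ACG", p)
    expect_equal(unname(enc[1L, ]), c(0.5, -1 / 3, 0))
})

test_that("profile symmetry, extremes and swap-negation hold", {
    # equal class frequencies -> 0
    p0 <- fitPositionProfile(c("AC", "GT", "AC", "GT"),
                             order = 1, labels = c(1, 1, 0, 0))
    expect_true(all(profileTable(p0) == 0))

    # disjoint classes -> +1 / -1 extremes
    p1 <- fitPositionProfile(c("CC", "CC", "AA"),
                             order = 1, labels = c(1, 1, 0))
    expect_equal(unname(profileTable(p1)[1, "C"]), 1)
    expect_equal(unname(profileTable(p1)[1, "A"]), -1)

    # swapping classes negates the table
    x <- c("ACGT", "AGGT", "TCGA", "ACGA")
    lab <- c(1, 1, 0, 0)
    pf <- fitPositionProfile(x, order = 2, labels = lab)
    pr <- fitPositionProfile(x, order = 2, labels = 1 - lab)
    expect_equal(profileTable(pf), -profileTable(pr))
    expect_true(all(abs(profileTable(pf)) <= 1))
})

test_that("dinucleotide profile encoding matches a hand-filled table", {
    # positives: CCA, CGA ; negatives: CCT, AGT (order-2 tokens at i, i+1)
    x <- c("CCA", "CGA", "CCT", "AGT")
    lab <- c(1, 1, 0, 0)
    p <- fitPositionProfile(x, order = 2, labels = lab)
    tab <- profileTable(p)
    expect_equal(unname(tab[1, "CC"]), 1 / 2 - 1 / 2)
    expect_equal(unname(tab[1, "CG"]), 1 / 2 - 0)
    expect_equal(unname(tab[1, "AG"]), 0 - 1 / 2)
    expect_equal(unname(tab[2, "CA"]), 1 / 2 - 0)
    expect_equal(unname(tab[2, "GA"]), 1 / 2 - 0)
    expect_equal(unname(tab[2, "CT"]), 0 - 1 / 2)
    expect_equal(unname(tab[2, "GT"]), 0 - 1 / 2)

    enc <- encodePSDSP("CCA", p)
    expect_equal(unname(enc[1L, ]), c(0, 1 / 2))
    # pairs containing N contribute zero
    encN <- encodePSDSP("CNA", p)
    expect_equal(unname(encN[1L, ]), c(0, 0))

    s138 <- randomSamples(3, window = 138, seed = 7,
                          labels = c("positive", "negative", "negative"))
    prof <- fitPositionProfile(s138, order = 2)
    expect_equal(ncol(encodePSDSP(s138, prof)), 152L)   # 15 + 138 - 1
    expect_error(encodePSDSP("ACGTACGT", prof), "length")
})

test_that("PSNSP dimensions follow the window and N maps to zero", {
    s <- randomSamples(4, window = 144, seed = 8,
                       labels = c("positive", "positive",
                                  "negative", "negative"))
    prof <- fitPositionProfile(s, order = 1)
    expect_equal(ncol(encodePSNSP(s, prof)), 159L)      # 15 + 144
    zeroProf <- prof
    zeroProf@table[] <- 0
    expect_true(all(encodePSNSP(s, zeroProf) == 0))
})

test_that("KNF yields 336 per-k-normalized frequencies", {
    expect_equal(ncol(encodeKNF(randomSamples(2, 150, seed = 1))), 336L)

    v <- encodeKNF("AAAA")
    expect_equal(unname(v[1, "k2_AA"]), 1)
    expect_equal(sum(v[1, 1:16]), 1)
    expect_equal(unname(v[1, "k3_AAA"]), 1)
    expect_equal(unname(v[1, "k4_AAAA"]), 1)

    v2 <- encodeKNF("ACGT")
    expect_equal(unname(v2[1, c("k2_AC", "k2_CG", "k2_GT")]),
                 rep(1 / 3, 3))
    expect_equal(sum(v2[1, 1:16] > 0), 3L)
})

test_that("KNF matches a naive counting oracle and blocks sum to one", {
    set.seed(21)
    for (i in 1:25) {
        L <- sample(10:50, 1)
        s <- paste(sample(c("A", "C", "G", "T", "N"), L, TRUE,
                          prob = c(.23, .23, .23, .23, .08)),
                   collapse = "")
        v <- encodeKNF(s)
        for (k in 2:4) {
            block <- v[1, grep(paste0("^k", k, "_"), colnames(v))]
            expect_equal(unname(block), unname(naiveKmerFreq(s, k)))
            if (sum(block) > 0) expect_equal(sum(block), 1)
        }
    }
})

test_that("KSNPF yields 80 per-spacing-normalized pair frequencies", {
    expect_equal(ncol(encodeKSNPF(randomSamples(2, 144, seed = 1))), 80L)

    v <- encodeKSNPF("AAA")
    expect_equal(unname(v[1, "s1_AA"]), 1)        # AXA
    expect_equal(sum(v[1, grep("^s1_", colnames(v))]), 1)

    v2 <- encodeKSNPF("ACGT")
    expect_equal(unname(v2[1, "s2_AT"]), 1)       # AXXT, single window
    # spacings longer than the sequence allows give all-zero blocks
    expect_true(all(v2[1, grep("^s3_|^s4_", colnames(v2))] == 0))
})

test_that("KSNPF matches a naive counting oracle", {
    set.seed(22)
    for (i in 1:25) {
        L <- sample(8:50, 1)
        s <- paste(sample(c("A", "C", "G", "T", "N"), L, TRUE,
                          prob = c(.23, .23, .23, .23, .08)),
                   collapse = "")
        v <- encodeKSNPF(s)
        for (k in 0:4) {
            block <- v[1, grep(paste0("^s", k, "_"), colnames(v))]
            expect_equal(unname(block), unname(naiveKspacedFreq(s, k)))
        }
    }
})

test_that("encoder dimensions match their closed forms across the window grid", {
    for (W in c(0L, 6L, 48L, 126L, 138L, 144L, 150L, 198L)) {
        s <- randomSamples(2, window = W, seed = W + 1,
                           labels = c("positive", "negative"))
        expect_equal(ncol(encodeOneHot(s)), 4L * (15L + W))
        expect_equal(ncol(encodeKNF(s)), 336L)
        expect_equal(ncol(encodeKSNPF(s)), 80L)
        p1 <- fitPositionProfile(s, order = 1)
        p2 <- fitPositionProfile(s, order = 2)
        expect_equal(ncol(encodePSNSP(s, p1)), 15L + W)
        expect_equal(ncol(encodePSDSP(s, p2)), 15L + W - 1L)
    }
})

test_that("padding contributes nothing to profile counts", {
    # padded N positions must not shift f(i, n) for either class
    seqs <- c(t1 = "CAACGGCTTCAGCTG", t2 = "CATCGGCTACAGCTG")
    sites <- scanCxxMotifs(seqs)
    smp <- extractSamples(seqs, sites, window = 6,
                          label = c("positive", "negative"))
    prof <- fitPositionProfile(smp, order = 1)
    expect_true(all(profileTable(prof)[1:3, ] == 0))    # all-N columns
    expect_true(all(profileTable(prof)[19:21, ] == 0))
})
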