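# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they share no code path with the implementation.

# Exhaustive CXX-run finder: tests every (start, repeat_count) pair for
# the C-at-phase property, full-triplet containment and per-phase
# maximality.
bruteForceScan <- function(s, minRepeats = 5L) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    hits <- list()
    for (start in seq_len(n)) {
        maxRc <- (n - start + 1L) %/% 3L
        if (maxRc < minRepeats) next
        for (rc in minRepeats:maxRc) {
            pos <- start + 3L * (seq_len(rc) - 1L)
            if (!all(ch[pos] == "C")) next
            leftC <- start - 3L >= 1L && ch[start - 3L] == "C"
            rpos <- start + 3L * rc
            rightC <- rpos + 2L <= n && ch[rpos] == "C"
            if (!leftC && !rightC)
                hits[[length(hits) + 1L]] <- c(start, rc)
        }
    }
    if (!length(hits))
        return(data.frame(start = integer(), repeat_count = integer()))
    m <- do.call(rbind, hits)
    m <- m[order(m[, 1L]), , drop = FALSE]
    data.frame(start = m[, 1L], repeat_count = m[, 2L])
}

scanAsFrame <- function(s, minRepeats = 5L) {
    g <- scanCxxMotifs(stats::setNames(s, "q"), minRepeats = minRepeats)
    data.frame(start = GenomicRanges::start(g),
               repeat_count = g$repeatCount)
}

# Tie-aware auROC by explicit pair counting (0.5 credit for ties).
pairCountAuc <- function(scores, labels) {
    pos <- scores[labels > 0]
    neg <- scores[labels <= 0]
    cmp <- outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b))
    mean(cmp)
}

# Naive k-mer frequency counter (N-containing windows skipped).
naiveKmerFreq <- function(s, k) {
    n <- nchar(s)
    kmers <- character()
    if (n >= k)
        kmers <- substring(s, seq_len(n - k + 1L),
                           seq_len(n - k + 1L) + k - 1L)
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    all4 <- sort(do.call(paste0, expand.grid(
        rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE]))
    cnt <- table(factor(kmers, levels = all4))
    if (sum(cnt) == 0) return(stats::setNames(rep(0, 4^k), all4))
    as.numeric(cnt) / sum(cnt)
}

# Naive k-spaced pair frequency counter.
naiveKspacedFreq <- function(s, k) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    pairs <- as.vector(t(outer(c("A", "C", "G", "T"),
                               c("A", "C", "G", "T"), paste0)))
    cnt <- stats::setNames(rep(0, 16L), pairs)
    nv <- 0L
    if (n >= k + 2L) for (i in seq_len(n - k - 1L)) {
        a <- ch[i]; b <- ch[i + k + 1L]
        if (a == "N" || b == "N") next
        cnt[paste0(a, b)] <- cnt[paste0(a, b)] + 1
        nv <- nv + 1L
    }
    if (nv == 0L) return(cnt)
    cnt / nv
}

# Valid PacesSamples with random flanks and planted 5-repeat motifs.
randomSamples <- function(n, window, seed = 1L,
                          labels = rep("unlabeled", n)) {
    set.seed(seed)
    L <- 15L + window
    M <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                nrow = n)
    M[, window / 2L + c(1L, 4L, 7L, 10L, 13L)] <- "C"
    new("PacesSamples",
        seqId = sprintf("r%03d", seq_len(n)),
        motifStart = rep(1L, n), window = as.integer(window),
        residues = apply(M, 1L, paste, collapse = ""),
        padLeft = rep(0L, n), padRight = rep(0L, n),
        label = factor(labels,
                       levels = c("negative", "positive", "unlabeled")),
        provenance = rep("fixture", n))
}

# A tiny handcrafted transcript + peak scenario used by dataset tests:
# layout string: motif (run of `reps` repeats) planted at `at` in an
# otherwise A/T background of length `len`.
plantMotif <- function(len, at, reps, fill = "A") {
    ch <- rep(fill, len)
    ch[at + 3L * (seq_len(reps) - 1L)] <- "C"
    paste(ch, collapse = "")
}

grPeak <- function(seqId, from, to, summit, id = "pk1") {
    GenomicRanges::GRanges(seqnames = seqId,
        ranges = IRanges::IRanges(start = from, end = to),
        summit = as.integer(summit), peakId = id)
}
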