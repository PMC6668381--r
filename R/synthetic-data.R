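# Synthetic benchmark generator: transcripts carrying one peak-embedded
# positive CXX motif each plus background (negative) motifs outside the
# peak, with two tunable class-distinguishing signal channels motivated by
# the feature-importance structure of real acetylation data: a G-rich
# flank composition around positive motifs (detectable by k-mer
# composition encodings) and an enriched dinucleotide immediately upstream
# of positive motifs (detectable by position-specific encodings).

# draw n residues with the given G probability (A, C, T share the rest)
drawResidues <- function(n, pG = 0.25) {
    sample(BASES, n, replace = TRUE,
           prob = c((1 - pG) / 3, (1 - pG) / 3, pG, (1 - pG) / 3))
}

#' Generate a synthetic acRIP-seq-like benchmark
#'
#' Emits transcripts, a peak table and ground-truth motif labels with a
#' class ratio of about \code{nPeaks : nBackgroundMotifs} (1:10 by
#' default, matching the ratio observed in real acetylation peak data).
#' Each transcript carries one positive motif at the centre of a
#' fixed-width peak and a share of the background motifs well outside it.
#' Positive flanks (the whole peak region) are drawn with G probability
#' \code{0.25 + signalStrength * gRichBias} and, with probability
#' \code{signalStrength}, the dinucleotide immediately upstream of the
#' positive motif is set to \code{proximalDinucleotide}; negative motifs
#' and all remaining sequence are i.i.d. uniform over ACGT. The X
#' positions of every motif are drawn from its class's flank
#' distribution. At \code{signalStrength = 0} the two classes are
#' generated identically. Accidental CXX runs that would confound the
#' ground truth are removed by point mutation, so scanning recovers
#' exactly the planted motifs.
#'
#' @param nPeaks number of peaks / positive motifs (default 500).
#' @param nBackgroundMotifs number of negative motifs (default 5000).
#' @param signalStrength gamma in [0, 1]; 0 = no class signal.
#' @param gRichBias excess G probability in positive flanks at full
#'   signal (default 0.2).
#' @param proximalDinucleotide 2-nt token planted immediately upstream of
#'   positive motifs (default \code{"GG"}).
#' @param motifRepeatProbs named probabilities of repeat counts 5..9 for
#'   planted motifs.
#' @param peakWidth peak width in nt (default 201; summit at the centre).
#' @param seed integer seed; generation is byte-identical under a fixed
#'   seed.
#' @return list with \code{sequences} (\code{DNAStringSet}),
#'   \code{peaks} (\code{GRanges} with \code{summit}, \code{peakId}), and
#'   \code{truth} (data.frame: seq_id, start (1-based), repeat_count,
#'   label).
#' @export
simulateAcetylationData <- function(nPeaks = 500L,
                                    nBackgroundMotifs = 5000L,
                                    signalStrength = 1,
                                    gRichBias = 0.2,
                                    proximalDinucleotide = "GG",
                                    motifRepeatProbs = c(
                                        "5" = 0.6, "6" = 0.2, "7" = 0.1,
                                        "8" = 0.06, "9" = 0.04),
                                    peakWidth = 201L,
                                    seed = 1L) {
    stopifnot(nPeaks >= 1L, nBackgroundMotifs >= 0L)
    if (signalStrength < 0 || signalStrength > 1)
        stop("signalStrength must lie in [0, 1]")
    if (gRichBias < 0 || 0.25 + gRichBias > 1)
        stop("gRichBias out of range")
    if (nchar(proximalDinucleotide) != 2L ||
        grepl("[^ACGT]", proximalDinucleotide))
        stop("proximalDinucleotide must be a 2-nt ACGT token")
    if (abs(sum(motifRepeatProbs) - 1) > 1e-8 ||
        !all(names(motifRepeatProbs) %in% as.character(5:9)))
        stop("motifRepeatProbs must be probabilities over repeat counts 5..9")
    peakWidth <- as.integer(peakWidth)
    if (peakWidth < 201L)
        stop("peakWidth must be at least 201 nt")

    # one negative motif per slot; slots are wide enough (200 nt) that no
    # encoder window (<= 165 nt) reaches a neighbouring planted motif,
    # which would otherwise imprint a spurious positional class signal
    slotWidth <- 200L
    buffer <- 90L       # keeps negative windows clear of peak composition
    pGpos <- 0.25 + signalStrength * gRichBias
    repeatChoices <- as.integer(names(motifRepeatProbs))

    nNegVec <- rep(nBackgroundMotifs %/% nPeaks, nPeaks)
    extra <- nBackgroundMotifs %% nPeaks
    if (extra > 0L) nNegVec[seq_len(extra)] <- nNegVec[seq_len(extra)] + 1L

    withSeed(seed, {
        seqList <- character(nPeaks)
        truth <- vector("list", nPeaks)
        peakRows <- vector("list", nPeaks)
        for (t in seq_len(nPeaks)) {
            nNeg <- nNegVec[t]
            nLeft <- nNeg %/% 2L + nNeg %% 2L
            nRight <- nNeg %/% 2L
            leftLen <- nLeft * slotWidth + buffer
            rightLen <- nRight * slotWidth + buffer
            txLen <- leftLen + peakWidth + rightLen
            tx <- drawResidues(txLen, 0.25)
            peakFrom <- leftLen + 1L
            peakTo <- leftLen + peakWidth
            tx[peakFrom:peakTo] <- drawResidues(peakWidth, pGpos)

            # positive motif anchored so its first 5-repeat window is
            # centred on the summit; any extra repeats continue downstream,
            # exactly as they do for negatives (which are trimmed to their
            # first five repeats), so trimming geometry carries no class
            # signal at signalStrength = 0
            rp <- sample(repeatChoices, 1L, prob = motifRepeatProbs)
            pStart <- leftLen + (peakWidth + 1L) %/% 2L - 7L
            tx[pStart + 3L * (seq_len(rp) - 1L)] <- "C"
            if (stats::runif(1L) < signalStrength)
                tx[(pStart - 2L):(pStart - 1L)] <-
                    strsplit(proximalDinucleotide, "")[[1L]]
            intended <- data.frame(
                start = pStart, repeat_count = rp,
                label = "positive", stringsAsFactors = FALSE)

            # negative motifs in slots flanking the peak
            if (nNeg > 0L) {
                slotStarts <- c(
                    (seq_len(nLeft) - 1L) * slotWidth,
                    leftLen + peakWidth + buffer +
                        (seq_len(nRight) - 1L) * slotWidth)
                for (s in slotStarts) {
                    rn <- sample(repeatChoices, 1L,
                                 prob = motifRepeatProbs)
                    nStart <- s + (slotWidth - 3L * rn) %/% 2L + 1L
                    tx[nStart + 3L * (seq_len(rn) - 1L)] <- "C"
                    intended <- rbind(intended, data.frame(
                        start = nStart, repeat_count = rn,
                        label = "negative", stringsAsFactors = FALSE))
                }
            }
            tx <- removeSpuriousRuns(tx, intended)
            id <- sprintf("tx%04d", t)
            seqList[t] <- paste(tx, collapse = "")
            names(seqList)[t] <- id
            intended$seq_id <- id
            truth[[t]] <- intended[, c("seq_id", "start", "repeat_count",
                                       "label")]
            peakRows[[t]] <- data.frame(
                seq_id = id, from = peakFrom, to = peakTo,
                summit = leftLen + (peakWidth + 1L) %/% 2L)
        }
        truth <- do.call(rbind, truth)
        pk <- do.call(rbind, peakRows)
        peaks <- GenomicRanges::GRanges(
            seqnames = pk$seq_id,
            ranges = IRanges::IRanges(start = pk$from, end = pk$to),
            summit = as.integer(pk$summit),
            peakId = sprintf("peak%04d", seq_len(nrow(pk))))
        seqs <- Biostrings::DNAStringSet(seqList)
        list(sequences = seqs, peaks = peaks, truth = truth)
    })
}

# Mutate away any maximal CXX run (>= 5 repeats) that is not exactly one
# of the intended motifs: pick a phase C of the offending run that is not
# an obligate C of any intended motif and flip it to T. Converges because
# every pass strictly reduces the number of non-intended C positions
# participating in long runs.
removeSpuriousRuns <- function(tx, intended) {
    obligate <- unlist(lapply(seq_len(nrow(intended)), function(r)
        intended$start[r] + 3L * (seq_len(intended$repeat_count[r]) - 1L)),
        use.names = FALSE)
    key <- paste(intended$start, intended$repeat_count)
    for (pass in seq_len(50L)) {
        found <- scanCxxMotifs(
            stats::setNames(paste(tx, collapse = ""), "x"))
        fkey <- paste(GenomicRanges::start(found), found$repeatCount)
        badRuns <- which(!fkey %in% key)
        if (!length(badRuns) && all(key %in% fkey)) return(tx)
        if (!length(badRuns))
            stop("intended motif lost during cleanup")    # not reachable
        for (b in badRuns) {
            p <- GenomicRanges::start(found)[b] +
                3L * (seq_len(found$repeatCount[b]) - 1L)
            p <- setdiff(p, obligate)
            if (!length(p))
                stop("cannot repair run overlapping intended motifs")
            tx[p[1L]] <- "T"
        }
    }
    stop("spurious-run cleanup did not converge")
}

#' Fixed-ratio labeled fixture
#'
#' A minimal labeled dataset with exact class counts (defaults matching a
#' 1160/10855 training partition), used for fold-composition and split
#' behavior checks. Samples are bare 15-nt motifs (window 0) with X
#' positions drawn uniformly.
#'
#' @param nPos,nNeg class counts (each >= 5).
#' @param seed integer seed.
#' @return a \linkS4class{PacesSamples} with window 0.
#' @export
makeRatioFixture <- function(nPos = 1160L, nNeg = 10855L, seed = 1L) {
    stopifnot(nPos >= 5L, nNeg >= 5L)
    n <- nPos + nNeg
    withSeed(seed, {
        M <- matrix(sample(BASES, n * 15L, replace = TRUE),
                    nrow = n, ncol = 15L)
        M[, c(1L, 4L, 7L, 10L, 13L)] <- "C"
        res <- apply(M, 1L, paste, collapse = "")
        new("PacesSamples",
            seqId = sprintf("fix%05d", seq_len(n)),
            motifStart = rep(1L, n), window = 0L,
            residues = res, padLeft = rep(0L, n), padRight = rep(0L, n),
            label = factor(rep(c("positive", "negative"), c(nPos, nNeg)),
                           levels = c("negative", "positive", "unlabeled")),
            provenance = rep("synthetic", n))
    })
}
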