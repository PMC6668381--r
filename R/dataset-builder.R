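# Construction of labeled positive/negative motif datasets from
# transcript sequences plus acRIP-seq peak annotations, and stratified
# train/test partitioning.

#' Build a labeled motif dataset from sequences and peaks
#'
#' Scans all transcripts for maximal repeating-CXX runs and labels them
#' against the peak annotation: runs fully inside a peak are positive
#' candidates, runs touching no peak are negatives, and runs partially
#' overlapping a peak are discarded as ambiguous. Each peak contributes at
#' most one positive: among all 5-repeat candidate windows of the runs it
#' fully contains, the window whose midpoint is nearest the peak summit is
#' selected (ties to the smaller start). Each outside run contributes one
#' negative, trimmed to its first five repeats.
#'
#' @param sequences transcript sequences (see
#'   \code{\link{normalizeSequences}}).
#' @param peaks a \link[GenomicRanges]{GRanges} with metadata column
#'   \code{summit} (1-based position within the peak), e.g. from
#'   \code{\link{readPeakTable}}.
#' @param minRepeats minimum CXX run length (default 5).
#' @param window total flank width W of the extracted samples (default 150,
#'   wide enough to be trimmed to any tuned encoder window).
#' @return a \linkS4class{PacesSamples} with positives first, then
#'   negatives; provenance records the source peak id or \code{"outside"}.
#' @importFrom GenomicRanges findOverlaps seqnames start width
#' @importFrom S4Vectors queryHits subjectHits
#' @export
buildDataset <- function(sequences, peaks, minRepeats = 5L, window = 150L) {
    sequences <- normalizeSequences(sequences)
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(peaks))),
                   names(sequences))
    if (length(bad))
        stop("peak(s) reference unknown sequence id(s): ",
             paste(bad, collapse = ", "))
    seqLen <- nchar(as.character(sequences))
    pk <- match(as.character(GenomicRanges::seqnames(peaks)),
                names(sequences))
    if (any(GenomicRanges::start(peaks) < 1L) ||
        any(GenomicRanges::end(peaks) > seqLen[pk]))
        stop("peak intervals must lie within their sequence bounds")
    if (is.null(peaks$summit))
        stop("peaks must carry a 'summit' metadata column")
    if (is.null(peaks$peakId))
        peaks$peakId <- sprintf("peak%d", seq_along(peaks))

    sites <- scanCxxMotifs(sequences, minRepeats = minRepeats)
    ovAny <- GenomicRanges::findOverlaps(sites, peaks)
    ovWithin <- GenomicRanges::findOverlaps(sites, peaks, type = "within")

    isOutside <- !seq_along(sites) %in% S4Vectors::queryHits(ovAny)

    # one positive window per peak, nearest the summit
    posList <- lapply(seq_along(peaks), function(j) {
        runIdx <- S4Vectors::queryHits(ovWithin)[
            S4Vectors::subjectHits(ovWithin) == j]
        if (!length(runIdx)) return(NULL)
        wins <- enumerateCandidateWindows(sites[runIdx])
        mid <- GenomicRanges::start(wins) + 7L
        d <- abs(mid - peaks$summit[j])
        pick <- order(d, GenomicRanges::start(wins))[1L]
        w <- wins[pick]
        S4Vectors::mcols(w) <- S4Vectors::DataFrame(
            repeatCount = 5L, peakId = peaks$peakId[j])
        w
    })
    posList <- posList[!vapply(posList, is.null, logical(1L))]
    posWins <- if (length(posList)) do.call(c, posList)
               else GenomicRanges::GRanges()

    negWins <- trimToFiveRepeats(sites[isOutside])

    pos <- extractSamples(sequences, posWins, window,
                          label = "positive",
                          provenance = if (length(posWins)) posWins$peakId
                                       else character())
    neg <- extractSamples(sequences, negWins, window,
                          label = "negative", provenance = "outside")
    append(pos, neg)
}

#' Stratified train/test split
#'
#' Randomly partitions a labeled dataset while preserving the class ratio:
#' within each class, \code{round(testFraction * n)} samples are drawn for
#' the test partition. Deterministic under a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param x a labeled \linkS4class{PacesSamples}.
#' @param testFraction fraction assigned to the test partition (0 < f < 1).
#' @param seed integer seed.
#' @return a list with elements \code{train} and \code{test}.
#' @export
splitTrainTest <- function(x, testFraction, seed) {
    stopifnot(is(x, "PacesSamples"),
              testFraction > 0, testFraction < 1)
    lab <- as.character(x@label)
    for (cl in c("positive", "negative"))
        if (sum(lab == cl) < 2L)
            stop("class '", cl, "' has fewer than 2 members")
    testIdx <- withSeed(seed, {
        unlist(lapply(unique(lab), function(cl) {
            idx <- which(lab == cl)
            sample(idx, round(testFraction * length(idx)))
        }), use.names = FALSE)
    })
    list(train = x[setdiff(seq_along(x@residues), testIdx)],
         test = x[sort(testIdx)])
}
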