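#' Scan sequences for repeating CXX motifs
#'
#' Locates every maximal run of obligate cytidines spaced three nucleotides
#' apart (C at positions p, p+3, p+6, ...), the repeating CXX pattern
#' characteristic of ac4C acetylation contexts. The two X positions of each
#' repeat may be any residue, including C and N, so a poly-C stretch
#' contains up to three phase-offset runs; each phase (p mod 3) is scanned
#' independently and maximality is per phase. A repeat is counted only when
#' its full CXX triplet lies within the sequence, so a reported site always
#' spans \code{3 * repeatCount} nt.
#'
#' @param seqs sequences in any form accepted by
#'   \code{\link{normalizeSequences}}.
#' @param minRepeats minimum run length to report (>= 2; default 5, the
#'   criterion used to define candidate acetylation motifs).
#' @return a \link[GenomicRanges]{GRanges} (1-based, inclusive) on the
#'   input sequence names, one range per maximal run, with metadata column
#'   \code{repeatCount}; ranges are sorted by sequence then start.
#' @examples
#' scanCxxMotifs(c(tx = "CAACGGCTTCAGCTG"))
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
#' @export
scanCxxMotifs <- function(seqs, minRepeats = 5L) {
    stopifnot(length(minRepeats) == 1L, minRepeats >= 2L)
    minRepeats <- as.integer(minRepeats)
    seqs <- normalizeSequences(seqs)
    out <- lapply(seq_along(seqs), function(k) {
        s <- as.character(seqs[[k]])
        n <- nchar(s)
        if (n < 3L * minRepeats) return(NULL)
        cpos <- as.integer(gregexpr("C", s, fixed = TRUE)[[1L]])
        if (length(cpos) == 0L || cpos[1L] == -1L) return(NULL)
        # a C can anchor a repeat only if its two X positions exist
        cpos <- cpos[cpos + 2L <= n]
        if (length(cpos) < minRepeats) return(NULL)
        res <- list()
        for (ph in 0:2) {
            p <- cpos[(cpos - 1L) %% 3L == ph]
            if (length(p) < minRepeats) next
            brk <- c(0L, which(diff(p) != 3L), length(p))
            for (r in seq_len(length(brk) - 1L)) {
                idx <- (brk[r] + 1L):brk[r + 1L]
                if (length(idx) >= minRepeats)
                    res[[length(res) + 1L]] <-
                        c(p[idx[1L]], length(idx))
            }
        }
        if (!length(res)) return(NULL)
        m <- do.call(rbind, res)
        m <- m[order(m[, 1L]), , drop = FALSE]
        data.frame(seq = names(seqs)[k], start = m[, 1L], rep = m[, 2L])
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        return(GenomicRanges::GRanges(
            seqnames = character(), ranges = IRanges::IRanges(),
            repeatCount = integer()))
    GenomicRanges::GRanges(
        seqnames = out$seq,
        ranges = IRanges::IRanges(start = out$start, width = 3L * out$rep),
        repeatCount = as.integer(out$rep))
}

#' Enumerate 5-repeat candidate windows of a motif run
#'
#' A maximal run of r >= 5 repeats contains r - 4 distinct windows of
#' exactly five consecutive CXX repeats, starting at offsets 0, 3, 6, ...
#' from the run start. At prediction time each window is scored and the
#' best one represents the run.
#'
#' @param sites a \link[GenomicRanges]{GRanges} from
#'   \code{\link{scanCxxMotifs}} with a \code{repeatCount} column, all
#'   entries >= 5.
#' @return a \code{GRanges} of 15-nt windows with columns
#'   \code{repeatCount} (always 5) and \code{siteIndex} (index of the
#'   parent run in \code{sites}).
#' @examples
#' run <- scanCxxMotifs(c(tx = "CAACAACAACAACAACAACAA"))
#' enumerateCandidateWindows(run)
#' @export
enumerateCandidateWindows <- function(sites) {
    rc <- sites$repeatCount
    if (any(rc < 5L))
        stop("all sites must have repeatCount >= 5")
    nWin <- rc - 4L
    parent <- rep(seq_along(sites), nWin)
    off <- unlist(lapply(nWin, function(k) 3L * (seq_len(k) - 1L)),
                  use.names = FALSE)
    GenomicRanges::GRanges(
        seqnames = rep(GenomicRanges::seqnames(sites), nWin),
        ranges = IRanges::IRanges(
            start = rep(GenomicRanges::start(sites), nWin) + off,
            width = 15L),
        repeatCount = 5L,
        siteIndex = parent)
}

#' Trim motif runs to their first five repeats
#'
#' @param sites a \code{GRanges} with \code{repeatCount >= 5}.
#' @return the same ranges restricted to width 15 with
#'   \code{repeatCount = 5}.
#' @export
trimToFiveRepeats <- function(sites) {
    if (any(sites$repeatCount < 5L))
        stop("all sites must have repeatCount >= 5")
    out <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(sites),
        ranges = IRanges::IRanges(
            start = GenomicRanges::start(sites), width = 15L),
        repeatCount = 5L)
    out
}

#' Extract fixed-width windowed samples around 5-repeat motifs
#'
#' Builds the sample strings used by all encoders: W/2 nt of upstream
#' flank, the 15-nt motif, and W/2 nt of downstream flank. Positions
#' falling outside the source sequence are filled with N and recorded in
#' the padding slots, so short transcripts remain usable.
#'
#' @param seqs sequences (normalized internally); names must cover all
#'   \code{seqnames(sites)}.
#' @param sites 15-nt motif windows (\code{repeatCount == 5}), e.g. from
#'   \code{\link{trimToFiveRepeats}} or
#'   \code{\link{enumerateCandidateWindows}}.
#' @param window total flanking width W; even, >= 0.
#' @param label sample label, one of \code{"unlabeled"}, \code{"positive"},
#'   \code{"negative"}, recycled.
#' @param provenance provenance string per sample, recycled.
#' @return a \linkS4class{PacesSamples} of length \code{length(sites)}.
#' @examples
#' sites <- scanCxxMotifs(c(tx = "CAACGGCTTCAGCTG"))
#' extractSamples(c(tx = "CAACGGCTTCAGCTG"), sites, window = 6)
#' @export
extractSamples <- function(seqs, sites, window, label = "unlabeled",
                           provenance = "query") {
    stopifnot(length(window) == 1L, window >= 0L)
    window <- as.integer(window)
    if (window %% 2L != 0L)
        stop("'window' must be even: it is split W/2 per flank")
    seqs <- normalizeSequences(seqs)
    if (!all(as.character(GenomicRanges::seqnames(sites)) %in% names(seqs)))
        stop("sites reference sequences absent from 'seqs'")
    if (length(sites) && any(GenomicRanges::width(sites) != 15L))
        stop("sites must be 15-nt 5-repeat windows; ",
             "use trimToFiveRepeats() or enumerateCandidateWindows()")
    half <- window %/% 2L
    id <- as.character(GenomicRanges::seqnames(sites))
    st <- GenomicRanges::start(sites)
    seqLen <- nchar(as.character(seqs))[match(id, names(seqs))]
    from <- st - half
    to <- st + 14L + half
    padL <- pmax(0L, 1L - from)
    padR <- pmax(0L, to - seqLen)
    core <- substring(as.character(seqs)[match(id, names(seqs))],
                      pmax(1L, from), pmin(seqLen, to))
    res <- paste0(strrep("N", padL), core, strrep("N", padR))
    lab <- factor(rep_len(label, length(sites)),
                  levels = c("negative", "positive", "unlabeled"))
    new("PacesSamples",
        seqId = id, motifStart = as.integer(st), window = window,
        residues = as.character(res), padLeft = as.integer(padL),
        padRight = as.integer(padR), label = lab,
        provenance = rep_len(provenance, length(sites)))
}

#' Narrow the flanks of existing samples
#'
#' Encoders use different flank widths (e.g. 138 nt for the dinucleotide
#' profile, 150 nt for k-mer frequencies); a sample set extracted at the
#' widest window is trimmed symmetrically for the narrower encoders.
#'
#' @param x a \linkS4class{PacesSamples}.
#' @param window target total flank width; even, \code{<= sampleWindow(x)}.
#' @return a \linkS4class{PacesSamples} at the requested window.
#' @export
trimSamples <- function(x, window) {
    stopifnot(is(x, "PacesSamples"), length(window) == 1L)
    window <- as.integer(window)
    if (window %% 2L != 0L) stop("'window' must be even")
    if (window > x@window)
        stop("cannot widen samples; re-extract from sequences instead")
    if (window == x@window) return(x)
    cut <- (x@window - window) %/% 2L
    L <- 15L + x@window
    initialize(x,
        window = window,
        residues = substr(x@residues, cut + 1L, L - cut),
        padLeft = pmax(0L, x@padLeft - cut),
        padRight = pmax(0L, x@padRight - cut))
}
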