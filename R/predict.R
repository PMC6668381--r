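# End-user prediction: scan query sequences, score every 5-repeat
# candidate window, resolve overlapping windows within a run to the
# highest-scoring one, and report calls against the chosen specificity
# threshold.

#' Predict ac4C acetylation motifs in query sequences
#'
#' Scans each query for maximal repeating-CXX runs; within a run of r
#' repeats, all r - 4 windows of five consecutive repeats are scored with
#' the meta-classifier and only the highest-scoring window represents the
#' run (ties to the smaller start). Every run yields one row; the
#' \code{call} column marks scores at or above the threshold for the
#' requested specificity. Motifs near transcript ends are scored with
#' N-padded flanks.
#'
#' @param model a trained \linkS4class{PacesModel}.
#' @param sequences query sequences (FASTA path via
#'   \code{\link{readSequences}}, character vector, or
#'   \code{DNAStringSet}); RNA (U) input is accepted.
#' @param specificity one of 0.99, 0.95, 0.90, 0.85 (default 0.99).
#' @param batchWarn warn when more sequences than this are submitted at
#'   once (default 50, mirroring the public server's cap; not enforced).
#' @return a \code{data.frame} with columns \code{seq_id}, \code{start},
#'   \code{end} (1-based inclusive, always spanning 15 nt),
#'   \code{repeat_count} (of the parent run), \code{score},
#'   \code{specificity}, \code{threshold}, \code{call}.
#' @export
pacesPredict <- function(model, sequences, specificity = 0.99,
                         batchWarn = 50L) {
    stopifnot(is(model, "PacesModel"))
    spKey <- as.character(specificity)
    if (!spKey %in% names(model@thresholds))
        stop("specificity must be one of: ",
             paste(names(model@thresholds), collapse = ", "))
    threshold <- model@thresholds[[spKey]]
    seqs <- normalizeSequences(sequences)
    if (length(seqs) > batchWarn)
        warning(length(seqs), " sequences submitted; processing all ",
                "(the public server caps batches at ", batchWarn, ")")
    empty <- data.frame(
        seq_id = character(), start = integer(), end = integer(),
        repeat_count = integer(), score = numeric(),
        specificity = numeric(), threshold = numeric(), call = logical())
    runs <- scanCxxMotifs(seqs, minRepeats = 5L)
    if (!length(runs)) return(empty)
    wins <- enumerateCandidateWindows(runs)
    samp <- extractSamples(seqs, wins, window = max(model@windows))
    score <- pacesScore(model, samp)
    best <- vapply(seq_along(runs), function(i) {
        j <- which(wins$siteIndex == i)
        j[order(-score[j], GenomicRanges::start(wins)[j])][1L]
    }, integer(1L))
    out <- data.frame(
        seq_id = as.character(GenomicRanges::seqnames(wins))[best],
        start = GenomicRanges::start(wins)[best],
        end = GenomicRanges::end(wins)[best],
        repeat_count = runs$repeatCount,
        score = score[best],
        specificity = as.numeric(specificity),
        threshold = threshold,
        call = score[best] >= threshold)
    rownames(out) <- NULL
    out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Write a prediction report
#'
#' TSV (default) keeps all columns; BED6 uses 0-based half-open
#' coordinates with the meta score scaled to 0-1000. A header comment
#' records the specificity setting and threshold.
#'
#' @param results data.frame from \code{\link{pacesPredict}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"bed"}.
#' @param callsOnly drop sub-threshold rows (server behavior); default
#'   FALSE.
#' @return the path, invisibly.
#' @export
writePredictions <- function(results, path, format = c("tsv", "bed"),
                             callsOnly = FALSE) {
    format <- match.arg(format)
    if (isTRUE(callsOnly)) results <- results[results$call, , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    sp <- if (nrow(results)) results$specificity[1L] else NA
    th <- if (nrow(results)) results$threshold[1L] else NA
    writeLines(sprintf("# paces predictions; specificity=%s threshold=%s",
                       format(sp), format(th)), con)
    if (format == "tsv") {
        utils::write.table(results, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        bed <- data.frame(
            chrom = results$seq_id,
            chromStart = results$start - 1L,
            chromEnd = results$end,
            name = sprintf("CXX_motif_%d", seq_len(nrow(results))),
            score = as.integer(round(results$score * 1000)),
            strand = "+")
        utils::write.table(bed, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' Read back a TSV prediction report
#'
#' Round-trip companion to \code{\link{writePredictions}}.
#'
#' @param path TSV report path.
#' @return the predictions data.frame.
#' @export
readPredictions <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    df$call <- as.logical(df$call)
    df
}
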