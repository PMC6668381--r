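# Readers and writers for the plain-text interchange formats: FASTA
# sequences, peak tables, sample tables and prediction reports.

#' Read query or transcript sequences from FASTA
#'
#' Accepts DNA or RNA alphabets (U is mapped to T) and wrapped lines;
#' record descriptions are truncated at the first whitespace to form ids.
#'
#' @param path FASTA file.
#' @return a normalized \link[Biostrings]{DNAStringSet}.
#' @importFrom Biostrings readBStringSet
#' @export
readSequences <- function(path) {
    x <- Biostrings::readBStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stop("duplicate sequence ids in ", path)
    normalizeSequences(x)
}

#' Read an acRIP-seq peak table
#'
#' Tab-separated file with header columns \code{seq_id}, \code{start},
#' \code{end}, \code{summit}; \code{start}/\code{end} are 0-based
#' half-open on the transcript and \code{summit} is a 0-based position
#' inside the peak (the convention of common peak callers). Lines starting
#' with \code{#} are ignored.
#'
#' @param path TSV file.
#' @return a \link[GenomicRanges]{GRanges} (1-based, inclusive) with
#'   metadata columns \code{summit} (1-based position) and \code{peakId}.
#' @importFrom utils read.table
#' @export
readPeakTable <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("seq_id", "start", "end", "summit")
    if (!all(need %in% names(df)))
        stop("peak table must have columns: ", paste(need, collapse = ", "))
    if (any(df$start >= df$end))
        stop("peak intervals must satisfy start < end (0-based half-open)")
    if (any(df$summit < df$start | df$summit >= df$end))
        stop("summit must lie within [start, end)")
    GenomicRanges::GRanges(
        seqnames = df$seq_id,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
        summit = as.integer(df$summit + 1L),
        peakId = if ("peak_id" %in% names(df)) df$peak_id
                 else sprintf("peak%d", seq_len(nrow(df))))
}

#' Write a peak table
#'
#' Inverse of \code{\link{readPeakTable}} (0-based half-open on disk).
#'
#' @param peaks a \code{GRanges} with \code{summit} (1-based) metadata.
#' @param path output TSV.
#' @importFrom utils write.table
#' @export
writePeakTable <- function(peaks, path) {
    df <- data.frame(
        seq_id = as.character(GenomicRanges::seqnames(peaks)),
        start = GenomicRanges::start(peaks) - 1L,
        end = GenomicRanges::end(peaks),
        summit = peaks$summit - 1L,
        peak_id = if (!is.null(peaks$peakId)) peaks$peakId
                  else sprintf("peak%d", seq_along(peaks)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# start/end 0-based half-open; summit 0-based", con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Write a labeled sample table
#'
#' @param x a \linkS4class{PacesSamples}.
#' @param path output TSV with columns seq_id, start (1-based),
#'   residues, label, provenance.
#' @param partition optional per-sample partition tag column.
#' @export
writeSamplesTable <- function(x, path, partition = NULL) {
    df <- data.frame(
        seq_id = x@seqId, start = x@motifStart, residues = x@residues,
        label = as.character(x@label), provenance = x@provenance)
    if (!is.null(partition)) df$partition <- partition
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Persist / restore a trained model
#'
#' The archive keeps both forests, the fitted dinucleotide profile, the
#' ensemble weights, the specificity-threshold table, the encoder windows
#' and the training seed, so reloaded models score identically.
#'
#' @param model a \linkS4class{PacesModel}.
#' @param path file path for the model archive.
#' @return \code{pacesLoadModel} returns the \linkS4class{PacesModel}.
#' @export
pacesSaveModel <- function(model, path) {
    stopifnot(is(model, "PacesModel"))
    saveRDS(model, path)
    invisible(path)
}

#' @rdname pacesSaveModel
#' @export
pacesLoadModel <- function(path) {
    model <- readRDS(path)
    if (!is(model, "PacesModel"))
        stop("'", path, "' does not contain a PacesModel")
    validObject(model)
    model
}
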