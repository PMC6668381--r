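# Accessors, subsetting and show methods for the core classes.

#' @rdname PacesSamples-class
#' @export
setMethod("sampleLabels", "PacesSamples", function(x) x@label)

#' @rdname PacesSamples-class
#' @export
setMethod("sampleWindow", "PacesSamples", function(x) x@window)

#' @rdname PacesSamples-class
#' @export
setMethod("sampleResidues", "PacesSamples", function(x) x@residues)

#' @rdname PacesSamples-class
#' @export
setMethod("sampleSeqId", "PacesSamples", function(x) x@seqId)

#' @rdname PacesSamples-class
#' @export
setMethod("sampleMotifStart", "PacesSamples", function(x) x@motifStart)

#' @rdname PacesSamples-class
#' @export
setMethod("positiveCount", "PacesSamples",
    function(x) sum(x@label == "positive"))

#' @rdname PacesSamples-class
#' @export
setMethod("negativeCount", "PacesSamples",
    function(x) sum(x@label == "negative"))

#' @describeIn PacesSamples-class logical matrix, TRUE where a position was
#'   N-padded because the window ran off the sequence end.
#' @export
setMethod("padMask", "PacesSamples", function(x) {
    L <- 15L + x@window
    n <- length(x@residues)
    pos <- matrix(seq_len(L), nrow = n, ncol = L, byrow = TRUE)
    pos <= x@padLeft | pos > L - x@padRight
})

#' @rdname PacesSamples-class
#' @export
setMethod("length", "PacesSamples", function(x) length(x@residues))

#' @rdname PacesSamples-class
#' @param i index vector for subsetting.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PacesSamples", function(x, i, j, ..., drop = FALSE) {
    initialize(x,
        seqId = x@seqId[i], motifStart = x@motifStart[i],
        residues = x@residues[i], padLeft = x@padLeft[i],
        padRight = x@padRight[i], label = x@label[i],
        provenance = x@provenance[i])
})

#' Concatenate sample sets
#'
#' @param x,values \linkS4class{PacesSamples} with identical window sizes.
#' @param after unused, kept for generic compatibility.
#' @return a combined \linkS4class{PacesSamples}.
#' @export
setMethod("append", c("PacesSamples", "PacesSamples"),
    function(x, values, after = length(x)) {
        stopifnot(x@window == values@window)
        initialize(x,
            seqId = c(x@seqId, values@seqId),
            motifStart = c(x@motifStart, values@motifStart),
            residues = c(x@residues, values@residues),
            padLeft = c(x@padLeft, values@padLeft),
            padRight = c(x@padRight, values@padRight),
            label = factor(c(as.character(x@label),
                             as.character(values@label)),
                           levels = levels(x@label)),
            provenance = c(x@provenance, values@provenance))
    })

setMethod("show", "PacesSamples", function(object) {
    cat(sprintf(
        "PacesSamples: %d samples, window W = %d (length %d nt)\n",
        length(object), object@window, 15L + object@window))
    cat(sprintf("  positive: %d  negative: %d  unlabeled: %d\n",
        sum(object@label == "positive"), sum(object@label == "negative"),
        sum(object@label == "unlabeled")))
})

#' @rdname PositionProfile-class
#' @export
setMethod("profileTable", "PositionProfile", function(x) x@table)

#' @rdname PositionProfile-class
#' @export
setMethod("profileOrder", "PositionProfile", function(x) x@order)

setMethod("show", "PositionProfile", function(object) {
    kind <- if (object@order == 1L) "nucleotide (PSNSP)"
            else "dinucleotide (PSDSP)"
    cat(sprintf(
        "PositionProfile: %s, %d positions x %d tokens (sample length %d)\n",
        kind, nrow(object@table), ncol(object@table), object@sampleLength))
    cat(sprintf("  fitted on %d positive / %d negative samples\n",
        object@nPos, object@nNeg))
})

setMethod("show", "ForestClassifier", function(object) {
    cat(sprintf(
        "ForestClassifier [%s]: %d trees, %d features, seed %d\n",
        object@encoding, object@nTrees, length(object@featureNames),
        object@seed))
})

#' @rdname PacesModel-class
#' @export
setMethod("modelWeights", "PacesModel", function(x) x@weights)

#' @rdname PacesModel-class
#' @export
setMethod("modelThresholds", "PacesModel", function(x) x@thresholds)

#' @rdname PacesModel-class
#' @export
setMethod("modelWindows", "PacesModel", function(x) x@windows)

setMethod("show", "PacesModel", function(object) {
    cat("PacesModel: PSDSP + KNF random-forest meta-classifier\n")
    cat(sprintf("  windows: PSDSP %d, KNF %d; trees: %d; seed: %d\n",
        object@windows[["psdsp"]], object@windows[["knf"]],
        object@forestPSDSP@nTrees, object@seed))
    cat(sprintf("  weights: psdsp %.2f, knf %.2f\n",
        object@weights[["psdsp"]], object@weights[["knf"]]))
    cat("  specificity thresholds:\n")
    for (s in names(object@thresholds))
        cat(sprintf("    %s%% -> %.4f\n",
            format(100 * as.numeric(s)), object@thresholds[[s]]))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf(
        "EvaluationReport: %d positives vs %d negatives\n",
        object@nPos, object@nNeg))
    cat(sprintf("  auROC = %.4f  auPRC = %.4f  BEP = %.4f\n",
        object@auROC, object@auPRC, object@bep))
})
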