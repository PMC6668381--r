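#' @import methods
#' @importFrom S4Vectors isSingleNumber
NULL

#' Windowed CXX-motif samples
#'
#' Container for fixed-width sequence windows centred on a 5-repeat CXX
#' motif (an obligate cytidine every third position, 15 nt in total), with
#' per-sample flanking sequence of \code{window/2} nt on each side. Windows
#' that run off a transcript end are padded with \code{N}; the number of
#' padded positions on each side is recorded so encoders can ignore them.
#'
#' @slot seqId character, source sequence identifier per sample.
#' @slot motifStart integer, 1-based start of the 5-repeat motif span on the
#'   source sequence.
#' @slot window integer scalar, total flanking width W (even); each sample
#'   string has length \code{15 + W}.
#' @slot residues character, the windowed sequences over \code{A,C,G,T,N}.
#' @slot padLeft,padRight integer, number of N-padded positions at each end.
#' @slot label factor with levels \code{negative}, \code{positive},
#'   \code{unlabeled}.
#' @slot provenance character, source peak id, \code{"outside"} or
#'   \code{"query"}.
#'
#' @exportClass PacesSamples
setClass("PacesSamples",
    representation(
        seqId = "character",
        motifStart = "integer",
        window = "integer",
        residues = "character",
        padLeft = "integer",
        padRight = "integer",
        label = "factor",
        provenance = "character"
    )
)

setValidity("PacesSamples", function(object) {
    n <- length(object@residues)
    W <- object@window
    msg <- character()
    if (length(W) != 1L || is.na(W) || W < 0L || W %% 2L != 0L)
        msg <- c(msg, "'window' must be a single even non-negative integer")
    lens <- c(length(object@seqId), length(object@motifStart),
              length(object@padLeft), length(object@padRight),
              length(object@label), length(object@provenance))
    if (any(lens != n))
        msg <- c(msg, "per-sample slots must all have the same length")
    if (!identical(levels(object@label),
                   c("negative", "positive", "unlabeled")))
        msg <- c(msg, "label levels must be negative/positive/unlabeled")
    if (length(msg)) return(msg)
    if (n > 0L) {
        if (any(nchar(object@residues) != 15L + W))
            return(sprintf("all residues must have length 15 + W = %d",
                           15L + W))
        core <- substr(object@residues, W / 2L + 1L, W / 2L + 15L)
        phase <- paste0(substr(core, 1L, 1L), substr(core, 4L, 4L),
                        substr(core, 7L, 7L), substr(core, 10L, 10L),
                        substr(core, 13L, 13L))
        if (any(phase != "CCCCC"))
            return("central 15 nt must carry C at positions 1,4,7,10,13")
        if (any(grepl("[^ACGTN]", object@residues)))
            return("residues restricted to the A,C,G,T,N alphabet")
    }
    TRUE
})

#' Position-specific sequence profile
#'
#' The fitted table f(i, n) = N+(i, n)/Np - N-(i, n)/Nn of per-position
#' token frequency differences between positive and negative training
#' samples. Order 1 uses the four nucleotides (PSNSP); order 2 uses the 16
#' overlapping dinucleotides (PSDSP). Tokens containing N are never counted.
#'
#' @slot order integer, 1 (nucleotide) or 2 (dinucleotide).
#' @slot table numeric matrix, rows = positions, columns = tokens, values in
#'   [-1, 1].
#' @slot nPos,nNeg integer, training class sizes Np and Nn.
#' @slot sampleLength integer, length of the sample strings the profile was
#'   fitted on (15 + W for windowed motif samples).
#'
#' @exportClass PositionProfile
setClass("PositionProfile",
    representation(
        order = "integer",
        table = "matrix",
        nPos = "integer",
        nNeg = "integer",
        sampleLength = "integer"
    )
)

setValidity("PositionProfile", function(object) {
    ord <- object@order
    if (length(ord) != 1L || !ord %in% c(1L, 2L))
        return("'order' must be 1 (nucleotide) or 2 (dinucleotide)")
    expCols <- if (ord == 1L) 4L else 16L
    if (ncol(object@table) != expCols)
        return(sprintf("profile of order %d needs %d token columns",
                       ord, expCols))
    expRows <- object@sampleLength - (ord - 1L)
    if (nrow(object@table) != expRows)
        return(sprintf("profile needs %d position rows for sample length %d",
                       expRows, object@sampleLength))
    if (any(!is.finite(object@table)) ||
        any(object@table < -1 - 1e-12) || any(object@table > 1 + 1e-12))
        return("profile values must lie in [-1, 1]")
    if (object@nPos < 1L || object@nNeg < 1L)
        return("both classes must be non-empty")
    TRUE
})

#' Fitted random-forest classifier for one encoding
#'
#' Thin wrapper around a fitted probability forest together with the
#' metadata needed to reproduce and apply it: the encoding name, tree
#' count, seed and the feature layout it expects.
#'
#' @slot encoding character, one of onehot/psnsp/psdsp/knf/ksnpf.
#' @slot fit the fitted \pkg{ranger} probability forest.
#' @slot nTrees integer, number of trees.
#' @slot seed integer, training seed.
#' @slot featureNames character, column layout of the training matrix.
#'
#' @exportClass ForestClassifier
setClass("ForestClassifier",
    representation(
        encoding = "character",
        fit = "ANY",
        nTrees = "integer",
        seed = "integer",
        featureNames = "character"
    )
)

#' Trained ac4C motif meta-classifier
#'
#' Bundles the two component forests (position-specific dinucleotide
#' profile encoding at window 138, k-nucleotide frequencies at window 150),
#' the fitted dinucleotide profile, the ensemble weights, and the
#' specificity-to-threshold calibration table derived from out-of-fold
#' negative training scores.
#'
#' @slot forestPSDSP,forestKNF \linkS4class{ForestClassifier} objects.
#' @slot profile \linkS4class{PositionProfile} (order 2) fitted on the full
#'   training set.
#' @slot weights named numeric, \code{c(psdsp=, knf=)}, non-negative, sum 1.
#' @slot thresholds named numeric, score cutoffs for nominal specificities
#'   \code{"0.99","0.95","0.9","0.85"}; non-increasing as specificity drops.
#' @slot windows named integer, flank widths per encoding.
#' @slot seed integer, master training seed.
#' @slot cvReports list of \linkS4class{EvaluationReport}s from the
#'   calibration cross-validation (per encoding plus \code{meta}).
#'
#' @exportClass PacesModel
setClass("PacesModel",
    representation(
        forestPSDSP = "ForestClassifier",
        forestKNF = "ForestClassifier",
        profile = "PositionProfile",
        weights = "numeric",
        thresholds = "numeric",
        windows = "integer",
        seed = "integer",
        cvReports = "list"
    )
)

setValidity("PacesModel", function(object) {
    w <- object@weights
    if (length(w) != 2L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
        return("weights must be two non-negative values summing to 1")
    th <- object@thresholds
    if (is.unsorted(rev(th)) && is.unsorted(th))
        return("thresholds must be monotone across specificities")
    sp <- as.numeric(names(th))
    if (any(diff(sp) < 0) && any(diff(th) > 1e-12))
        return("threshold must not increase as specificity decreases")
    TRUE
})

#' ROC / precision-recall evaluation report
#'
#' Classifier performance summary from a grouped-threshold sweep: ROC
#' points with trapezoid auROC (equal to the normalized Mann-Whitney U
#' statistic), precision-recall points with trapezoid auPRC, and the
#' break-even point where precision equals recall (linear interpolation).
#'
#' @slot rocPoints numeric matrix with columns fpr, tpr.
#' @slot auROC,auPRC,bep numeric scalars in [0, 1].
#' @slot prPoints numeric matrix with columns recall, precision.
#' @slot nPos,nNeg integer class sizes.
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    representation(
        rocPoints = "matrix",
        auROC = "numeric",
        prPoints = "matrix",
        auPRC = "numeric",
        bep = "numeric",
        nPos = "integer",
        nNeg = "integer"
    )
)
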