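#' @rdname PacesSamples-class
#' @param x,object a \linkS4class{PacesSamples} object.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname PacesSamples-class
#' @export
setGeneric("sampleWindow", function(x) standardGeneric("sampleWindow"))

#' @rdname PacesSamples-class
#' @export
setGeneric("sampleResidues", function(x) standardGeneric("sampleResidues"))

#' @rdname PacesSamples-class
#' @export
setGeneric("sampleSeqId", function(x) standardGeneric("sampleSeqId"))

#' @rdname PacesSamples-class
#' @export
setGeneric("sampleMotifStart", function(x) standardGeneric("sampleMotifStart"))

#' @rdname PacesSamples-class
#' @export
setGeneric("padMask", function(x) standardGeneric("padMask"))

#' @rdname PacesSamples-class
#' @export
setGeneric("positiveCount", function(x) standardGeneric("positiveCount"))

#' @rdname PacesSamples-class
#' @export
setGeneric("negativeCount", function(x) standardGeneric("negativeCount"))

#' @rdname PositionProfile-class
#' @param x a \linkS4class{PositionProfile} object.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname PositionProfile-class
#' @export
setGeneric("profileOrder", function(x) standardGeneric("profileOrder"))

#' @rdname PacesModel-class
#' @param x a \linkS4class{PacesModel} object.
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname PacesModel-class
#' @export
setGeneric("modelThresholds", function(x) standardGeneric("modelThresholds"))

#' @rdname PacesModel-class
#' @export
setGeneric("modelWindows", function(x) standardGeneric("modelWindows"))
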