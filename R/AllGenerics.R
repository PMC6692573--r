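#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' @export
setGeneric("constructIds", function(x) standardGeneric("constructIds"))

#' @export
setGeneric("regSeqs", function(x) standardGeneric("regSeqs"))

#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @export
setGeneric("reporterContexts", function(x) standardGeneric("reporterContexts"))

#' @export
setGeneric("barcodeIndex", function(x) standardGeneric("barcodeIndex"))

#' @export
setGeneric("primaryTss", function(x) standardGeneric("primaryTss"))

#' @export
setGeneric("secondaryTss", function(x) standardGeneric("secondaryTss"))

#' @export
setGeneric("tssClusters", function(x) standardGeneric("tssClusters"))

#' @export
setGeneric("pwmProbs", function(x) standardGeneric("pwmProbs"))

#' @export
setGeneric("pwmWidth", function(x) standardGeneric("pwmWidth"))

#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))
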