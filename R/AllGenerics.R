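#' @rdname markerAlignment
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @rdname markerAlignment
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname markerAlignment
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname markerAlignment
#' @export
setGeneric("markerName", function(x) standardGeneric("markerName"))

#' @rdname collapseHaplotypes
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname collapseHaplotypes
#' @export
setGeneric("haplotypeMembers", function(x) standardGeneric("haplotypeMembers"))

#' @rdname buildNetworks
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname buildNetworks
#' @export
setGeneric("componentPopulations",
           function(x) standardGeneric("componentPopulations"))

#' @rdname groupDistanceSummary
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

#' @rdname assignRanks
#' @export
setGeneric("rankTable", function(x) standardGeneric("rankTable"))

#' @rdname evaluateLines
#' @export
setGeneric("linesOfEvidence", function(x) standardGeneric("linesOfEvidence"))
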