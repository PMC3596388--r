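#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("patientLabels", function(x) standardGeneric("patientLabels"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setGeneric("biclusterGenes", function(x) standardGeneric("biclusterGenes"))

#' @rdname accessors
#' @export
setGeneric("timeWindow", function(x) standardGeneric("timeWindow"))

#' @rdname accessors
#' @export
setGeneric("stateProfile", function(x) standardGeneric("stateProfile"))

#' @rdname accessors
#' @export
setGeneric("biclusterScore", function(x) standardGeneric("biclusterScore"))

#' @rdname accessors
#' @export
setGeneric("profileBiclusters", function(x) standardGeneric("profileBiclusters"))

#' @rdname accessors
#' @export
setGeneric("profileWeights", function(x) standardGeneric("profileWeights"))

#' @rdname accessors
#' @export
setGeneric("simMatrix", function(x) standardGeneric("simMatrix"))

#' @rdname accessors
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))

#' @rdname accessors
#' @export
setGeneric("cvPredictions", function(x) standardGeneric("cvPredictions"))
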