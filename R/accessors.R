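#' Accessors for tsnet classes
#'
#' Small read-only accessors so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @return The corresponding component (see the slot documentation of each
#'   class).
#' @name accessors
NULL

#' @rdname accessors
setMethod("patientIds", "ExpressionDataset", function(x) x@patientIds)
#' @rdname accessors
setMethod("geneIds", "ExpressionDataset", function(x) x@geneIds)
#' @rdname accessors
setMethod("timePoints", "ExpressionDataset", function(x) x@timePoints)
#' @rdname accessors
setMethod("exprValues", "ExpressionDataset", function(x) x@values)
#' @rdname accessors
setMethod("missingMask", "ExpressionDataset", function(x) x@mask)
#' @rdname accessors
setMethod("patientLabels", "ExpressionDataset",
          function(x) setNames(x@labels, x@patientIds))

#' @rdname accessors
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("geneIds", "GeneStateMatrix", function(x) x@geneIds)
#' @rdname accessors
setMethod("timePoints", "GeneStateMatrix", function(x) x@timePoints)
#' @rdname accessors
setMethod("stateMatrix", "GeneStateMatrix", function(x) x@states)
#' @rdname accessors
setMethod("nStates", "GeneStateMatrix", function(x) x@Q)
#' @rdname accessors
setMethod("nStates", "HmmGmmModel", function(x) x@Q)
#' @rdname accessors
setMethod("geneIds", "HmmGmmModel", function(x) x@geneIds)

#' @rdname accessors
setMethod("biclusterGenes", "Bicluster", function(x) x@genes)
#' @rdname accessors
setMethod("timeWindow", "Bicluster", function(x) c(x@tStart, x@tEnd))
#' @rdname accessors
setMethod("stateProfile", "Bicluster", function(x) x@profile)
#' @rdname accessors
setMethod("biclusterScore", "Bicluster", function(x) x@score)

#' @rdname accessors
setMethod("patientIds", "PatientProfile", function(x) x@patientId)
#' @rdname accessors
setMethod("profileBiclusters", "PatientProfile", function(x) x@biclusters)
#' @rdname accessors
setMethod("profileWeights", "PatientProfile", function(x) x@weights)

#' @rdname accessors
setMethod("simMatrix", "SimilarityKernel", function(x) x@sim)
#' @rdname accessors
setMethod("patientIds", "SimilarityKernel", function(x) rownames(x@sim))

#' @rdname accessors
setMethod("cvSummary", "CvReport", function(x) x@summary)
#' @rdname accessors
setMethod("cvPredictions", "CvReport", function(x) x@predictions)

setMethod("show", "ExpressionDataset", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionDataset: %d patients x %d genes x %d time points\n",
              d[1], d[2], d[3]))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(!object@mask),
              100 * mean(!object@mask)))
  if (length(object@labels))
    cat(sprintf("  labels: %d good (+1) / %d bad (-1) responders\n",
                sum(object@labels == 1L), sum(object@labels == -1L)))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d nodes, %d undirected edges\n",
              length(object@nodes), nrow(object@edges)))
})

setMethod("show", "GeneStateMatrix", function(object) {
  cat(sprintf("GeneStateMatrix: %d genes x %d time points, Q = %d states\n",
              length(object@geneIds), length(object@timePoints), object@Q))
})

setMethod("show", "Bicluster", function(object) {
  cat(sprintf("Bicluster: %d genes, window [%d, %d], profile {%s}%s\n",
              length(object@genes), object@tStart, object@tEnd,
              paste(object@profile, collapse = ","),
              if (is.na(object@score)) "" else
                sprintf(", score %.4g", object@score)))
})

setMethod("show", "PatientProfile", function(object) {
  cat(sprintf("PatientProfile '%s': %d biclusters\n", object@patientId,
              length(object@biclusters)))
})

setMethod("show", "HmmGmmModel", function(object) {
  cat(sprintf("HmmGmmModel: Q = %d states, %d mixture components (genes)\n",
              object@Q, length(object@geneIds)))
  if (length(object@logLik))
    cat(sprintf("  EM iterations: %d, final logLik %.4f\n",
                length(object@logLik), tail(object@logLik, 1L)))
})

setMethod("show", "SimilarityKernel", function(object) {
  cat(sprintf("SimilarityKernel: %d x %d patient similarity matrix\n",
              nrow(object@sim), ncol(object@sim)))
})

setMethod("show", "SvmSolution", function(object) {
  cat(sprintf("SvmSolution: %d points, %d support vectors, C = %g, b = %.4g\n",
              length(object@alphas), length(object@supportIndex), object@cost,
              object@bias))
})

setMethod("show", "CvReport", function(object) {
  s <- object@settings
  cat(sprintf("CvReport: %s repetitions x %s-fold cross-validation\n",
              s$reps, s$folds))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d modules, %d patients, seed %d\n",
              length(object@moduleGenes), length(object@states), object@seed))
})
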