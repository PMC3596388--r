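#' @import methods
#' @importFrom stats dnorm phyper rbinom rnorm runif sd setNames
#' @importFrom utils head tail
NULL

#' Patient x gene x time expression container
#'
#' Holds real-valued expression trajectories for a cohort: one value per
#' (patient, gene, time point), a missingness mask, and a binary response label
#' per patient (+1 = good responder, -1 = bad responder).
#'
#' @slot patientIds character, unique patient identifiers.
#' @slot geneIds character, unique gene identifiers.
#' @slot timePoints integer, strictly increasing 1-based time indices.
#' @slot values numeric 3-d array, patient x gene x time.
#' @slot mask logical array of the same shape; TRUE where a value is present.
#' @slot labels integer vector in \{+1, -1\}, one per patient.
#' @exportClass ExpressionDataset
setClass("ExpressionDataset",
  representation(
    patientIds = "character",
    geneIds    = "character",
    timePoints = "integer",
    values     = "array",
    mask       = "array",
    labels     = "integer"
  )
)

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  np <- length(object@patientIds); ng <- length(object@geneIds)
  nt <- length(object@timePoints)
  if (anyDuplicated(object@patientIds)) msg <- c(msg, "patientIds must be unique")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "geneIds must be unique")
  if (nt < 1L || is.unsorted(object@timePoints, strictly = TRUE))
    msg <- c(msg, "timePoints must be strictly increasing")
  if (!identical(dim(object@values), c(np, ng, nt)))
    msg <- c(msg, "values must be a patient x gene x time array")
  if (!identical(dim(object@mask), c(np, ng, nt)))
    msg <- c(msg, "mask must match the shape of values")
  if (any(!is.finite(object@values[object@mask])))
    msg <- c(msg, "values must be finite wherever mask marks present")
  if (length(object@labels) &&
      (length(object@labels) != np || !all(object@labels %in% c(-1L, 1L))))
    msg <- c(msg, "labels must be one of +1/-1 per patient")
  if (length(msg)) msg else TRUE
})

#' Undirected simple graph over gene identifiers
#'
#' @slot nodes character, gene identifiers (the universe kept for the graph).
#' @slot edges 2-column character matrix of unordered gene pairs; no self-loops
#'   or duplicates, endpoints drawn from \code{nodes}.
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(nodes = "character", edges = "matrix")
)

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (anyDuplicated(object@nodes)) msg <- c(msg, "nodes must be unique")
  if (ncol(e) != 2L) msg <- c(msg, "edges must have 2 columns")
  else if (nrow(e)) {
    if (!all(e %in% object@nodes)) msg <- c(msg, "edge endpoints must be nodes")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loops are not allowed")
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Discrete gene-state matrix for one patient
#'
#' @slot geneIds character.
#' @slot timePoints integer, 1-based time indices.
#' @slot states integer matrix gene x time with entries in 1..Q.
#' @slot Q integer, number of states.
#' @exportClass GeneStateMatrix
setClass("GeneStateMatrix",
  representation(geneIds = "character", timePoints = "integer",
                 states = "matrix", Q = "integer")
)

setValidity("GeneStateMatrix", function(object) {
  msg <- character()
  s <- object@states
  if (!identical(dim(s), c(length(object@geneIds), length(object@timePoints))))
    msg <- c(msg, "states must be gene x time")
  if (length(s) && (any(s < 1L) || any(s > object@Q)))
    msg <- c(msg, "states must lie in 1..Q")
  if (length(msg)) msg else TRUE
})

#' Temporal bicluster: gene set x contiguous time window with shared profile
#'
#' @slot genes character, member genes (G).
#' @slot tStart,tEnd integer, inclusive 1-based window bounds (T).
#' @slot profile integer, one state per time point of the window (S).
#' @slot score numeric, raw network-connectivity preference (PPIScore).
#' @exportClass Bicluster
setClass("Bicluster",
  representation(genes = "character", tStart = "integer", tEnd = "integer",
                 profile = "integer", score = "numeric"),
  prototype(score = NA_real_)
)

setValidity("Bicluster", function(object) {
  msg <- character()
  w <- object@tEnd - object@tStart + 1L
  if (w < 1L) msg <- c(msg, "tEnd must be >= tStart")
  if (length(object@profile) != w)
    msg <- c(msg, "profile length must equal the window length")
  if (!length(object@genes)) msg <- c(msg, "genes must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Bicluster profile of one patient with normalized weights
#'
#' @slot patientId character scalar.
#' @slot biclusters list of \linkS4class{Bicluster}.
#' @slot weights numeric, nonnegative, summing to 1 when biclusters are present.
#' @exportClass PatientProfile
setClass("PatientProfile",
  representation(patientId = "character", biclusters = "list",
                 weights = "numeric")
)

setValidity("PatientProfile", function(object) {
  msg <- character()
  n <- length(object@biclusters)
  if (length(object@weights) != n)
    msg <- c(msg, "one weight per bicluster required")
  if (n && any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (n && abs(sum(object@weights) - 1) > 1e-8)
    msg <- c(msg, "weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Hidden Markov model with Gaussian-mixture emissions
#'
#' Per hidden state j the emission density is a mixture over one Gaussian
#' component per gene: b_j(x) = sum_i w[j,i] * N(x; mu[j,i], sigma[j,i]).
#'
#' @slot Q integer, number of hidden states.
#' @slot pi numeric length-Q initial distribution.
#' @slot A Q x Q transition matrix, rows sum to 1.
#' @slot w Q x n mixture weights, rows sum to 1.
#' @slot mu,sigma Q x n component means and standard deviations.
#' @slot geneIds character length n; component i is paired with gene i.
#' @slot sigmaFloor numeric, lower clamp for sigma.
#' @slot logLik numeric, per-iteration total log-likelihood trace from EM.
#' @exportClass HmmGmmModel
setClass("HmmGmmModel",
  representation(Q = "integer", pi = "numeric", A = "matrix", w = "matrix",
                 mu = "matrix", sigma = "matrix", geneIds = "character",
                 sigmaFloor = "numeric", logLik = "numeric"),
  prototype(logLik = numeric())
)

setValidity("HmmGmmModel", function(object) {
  msg <- character()
  Q <- object@Q; n <- length(object@geneIds)
  if (length(object@pi) != Q || abs(sum(object@pi) - 1) > 1e-8)
    msg <- c(msg, "pi must be length Q and sum to 1")
  if (!identical(dim(object@A), c(Q, Q)) ||
      any(abs(rowSums(object@A) - 1) > 1e-8))
    msg <- c(msg, "A must be Q x Q with unit row sums")
  for (nm in c("w", "mu", "sigma"))
    if (!identical(dim(slot(object, nm)), c(Q, n)))
      msg <- c(msg, sprintf("%s must be Q x n", nm))
  if (identical(dim(object@w), c(Q, n)) && n &&
      any(abs(rowSums(object@w) - 1) > 1e-8))
    msg <- c(msg, "rows of w must sum to 1")
  if (identical(dim(object@sigma), c(Q, n)) && n &&
      any(object@sigma < object@sigmaFloor - 1e-12))
    msg <- c(msg, "sigma must be >= sigmaFloor")
  if (length(msg)) msg else TRUE
})

#' Symmetric patient-by-patient similarity kernel
#'
#' @slot sim numeric matrix with unit diagonal, entries in [0, 1], patient ids
#'   as dimnames.
#' @exportClass SimilarityKernel
setClass("SimilarityKernel", representation(sim = "matrix"))

setValidity("SimilarityKernel", function(object) {
  s <- object@sim
  msg <- character()
  if (nrow(s) != ncol(s) || !isTRUE(all.equal(s, t(s), tolerance = 0)))
    msg <- c(msg, "kernel must be exactly symmetric")
  if (any(abs(diag(s) - 1) > 1e-9)) msg <- c(msg, "diagonal must be 1")
  if (any(s < -1e-12) || any(s > 1 + 1e-12)) msg <- c(msg, "entries must be in [0,1]")
  if (is.null(rownames(s))) msg <- c(msg, "patient ids required as dimnames")
  if (length(msg)) msg else TRUE
})

#' Soft-margin SVM dual solution on a precomputed kernel
#'
#' @slot alphas numeric multipliers, 0 <= alpha_i <= C.
#' @slot bias numeric scalar.
#' @slot labels integer +1/-1 per training point.
#' @slot C numeric box constraint.
#' @slot kernel the (PSD-projected) training kernel actually solved.
#' @slot supportIndex integer indices with alpha above threshold.
#' @exportClass SvmSolution
setClass("SvmSolution",
  representation(alphas = "numeric", bias = "numeric", labels = "integer",
                 cost = "numeric", kernel = "matrix", supportIndex = "integer")
)

setValidity("SvmSolution", function(object) {
  msg <- character()
  a <- object@alphas
  if (any(a < -1e-8) || any(a > object@cost + 1e-8))
    msg <- c(msg, "alphas must satisfy 0 <= alpha <= C")
  if (abs(sum(a * object@labels)) > 1e-8)
    msg <- c(msg, "equality constraint sum(alpha*y) = 0 violated")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' @slot predictions data.frame with columns rep, fold, patient, truth,
#'   predicted.
#' @slot perRep data.frame of per-repetition metrics.
#' @slot summary data.frame with mean and sd per metric.
#' @slot settings list echoing the configuration used.
#' @exportClass CvReport
setClass("CvReport",
  representation(predictions = "data.frame", perRep = "data.frame",
                 summary = "data.frame", settings = "list")
)

#' Ground truth of a synthetic cohort
#'
#' @slot moduleGenes named list of gene-id vectors (discriminative and decoy
#'   modules).
#' @slot programs named list; per module, a list with the per-class state
#'   programs over 1..T.
#' @slot states list of true gene x time state matrices, one per patient.
#' @slot plantedBiclusters list (per patient) of \linkS4class{Bicluster}
#'   objects planted by construction.
#' @slot labels integer per patient.
#' @slot seed integer generator seed.
#' @slot params list of generator parameters.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(moduleGenes = "list", programs = "list", states = "list",
                 plantedBiclusters = "list", labels = "integer",
                 seed = "integer", params = "list")
)
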