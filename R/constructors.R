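#' Construct an ExpressionDataset
#'
#' @param values numeric patient x gene x time array.
#' @param patientIds,geneIds,timePoints identifiers for the three axes; taken
#'   from dimnames of \code{values} when omitted.
#' @param mask logical array of the same shape, TRUE = present. Defaults to
#'   non-NA entries of \code{values}.
#' @param labels optional integer/numeric vector of +1/-1 per patient.
#' @return An \linkS4class{ExpressionDataset}.
#' @export
ExpressionDataset <- function(values, patientIds = NULL, geneIds = NULL,
                              timePoints = NULL, mask = NULL, labels = integer()) {
  stopifnot(length(dim(values)) == 3L)
  if (is.null(patientIds)) patientIds <- dimnames(values)[[1L]]
  if (is.null(patientIds)) patientIds <- paste0("P", seq_len(dim(values)[1L]))
  if (is.null(geneIds)) geneIds <- dimnames(values)[[2L]]
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(dim(values)[2L]))
  if (is.null(timePoints)) timePoints <- seq_len(dim(values)[3L])
  if (is.null(mask)) mask <- !is.na(values)
  storage.mode(values) <- "double"
  storage.mode(mask) <- "logical"
  dimnames(values) <- dimnames(mask) <-
    list(patientIds, geneIds, as.character(timePoints))
  new("ExpressionDataset", patientIds = as.character(patientIds),
      geneIds = as.character(geneIds), timePoints = as.integer(timePoints),
      values = values, mask = mask, labels = as.integer(labels))
}

#' Construct an InteractionNetwork
#'
#' Self-loops and duplicate edges are removed silently; use
#' \code{\link{readNetwork}} for the logged variant.
#'
#' @param nodes character gene identifiers.
#' @param edges 2-column character matrix (or data.frame) of gene pairs.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(nodes, edges = matrix(character(), 0L, 2L)) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L && length(edges) == 0L)
    edges <- matrix(character(), 0L, 2L)
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L])), , drop = FALSE]
    o <- order(edges[, 1L], edges[, 2L])
    edges <- edges[o, , drop = FALSE]
  }
  dimnames(edges) <- NULL
  new("InteractionNetwork", nodes = as.character(nodes), edges = edges)
}

#' Construct a GeneStateMatrix
#'
#' @param states integer gene x time matrix with entries in 1..Q.
#' @param geneIds,timePoints axis identifiers; default from dimnames/indices.
#' @param Q number of states; defaults to \code{max(states)}.
#' @return A \linkS4class{GeneStateMatrix}.
#' @export
GeneStateMatrix <- function(states, geneIds = NULL, timePoints = NULL, Q = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(geneIds)) geneIds <- rownames(states)
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(states)))
  if (is.null(timePoints)) timePoints <- seq_len(ncol(states))
  if (is.null(Q)) Q <- max(states, 1L)
  dimnames(states) <- list(geneIds, as.character(timePoints))
  new("GeneStateMatrix", geneIds = as.character(geneIds),
      timePoints = as.integer(timePoints), states = states, Q = as.integer(Q))
}

#' Construct a Bicluster
#'
#' @param genes character member genes.
#' @param tStart,tEnd inclusive 1-based window bounds.
#' @param profile integer state per window time point.
#' @param score optional raw network preference score.
#' @return A \linkS4class{Bicluster}.
#' @export
Bicluster <- function(genes, tStart, tEnd, profile, score = NA_real_) {
  new("Bicluster", genes = as.character(genes), tStart = as.integer(tStart),
      tEnd = as.integer(tEnd), profile = as.integer(profile),
      score = as.numeric(score))
}

#' Construct a PatientProfile
#'
#' @param patientId patient identifier.
#' @param biclusters list of \linkS4class{Bicluster}.
#' @param weights normalized weights (sum to 1 if any biclusters); defaults to
#'   uniform.
#' @return A \linkS4class{PatientProfile}.
#' @export
PatientProfile <- function(patientId, biclusters = list(), weights = NULL) {
  n <- length(biclusters)
  if (is.null(weights))
    weights <- if (n) rep(1 / n, n) else numeric()
  new("PatientProfile", patientId = as.character(patientId),
      biclusters = biclusters, weights = as.numeric(weights))
}
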