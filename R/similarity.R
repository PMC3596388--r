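# Indicator matrices of a profile's biclusters over a shared coordinate
# system: gene membership (nB x nGenes) and time-stamped state tokens
# (nB x T*Q), plus bicluster sizes |B| = |G| * |J|.
.profileMats <- function(profile, geneLevels, T, Q) {
  nB <- length(profile@biclusters)
  GM <- matrix(0, nB, length(geneLevels))
  JM <- matrix(0, nB, T * Q)
  size <- numeric(nB)
  for (i in seq_len(nB)) {
    b <- profile@biclusters[[i]]
    GM[i, match(b@genes, geneLevels)] <- 1
    ts <- b@tStart:b@tEnd
    JM[i, (ts - 1L) * Q + b@profile] <- 1
    size[i] <- length(b@genes) * length(ts)
  }
  list(GM = GM, JM = JM, size = size, w = profile@weights)
}

# Pairwise bicluster Jaccard matrix between two profiles' mats.
.jaccardMatrix <- function(m1, m2) {
  num <- tcrossprod(m1$GM, m2$GM) * tcrossprod(m1$JM, m2$JM)
  den <- outer(m1$size, m2$size, "+") - num
  num / den
}

# Similarity from precomputed profile mats (shared coordinate system).
# Profiles with zero biclusters compare as 0 (self-similarity 1 is handled
# by the caller, which knows identity).
.simFromMats <- function(m1, m2, aggregation = "bestmatch") {
  if (!nrow(m1$GM) || !nrow(m2$GM)) return(0)
  S <- .jaccardMatrix(m1, m2)
  if (aggregation == "bestmatch")
    (sum(m1$w * apply(S, 1L, max)) + sum(m2$w * apply(S, 2L, max))) / 2
  else
    as.numeric(m1$w %*% S %*% m2$w)
}

.pairCoords <- function(p1, p2) {
  geneLevels <- sort(unique(c(
    unlist(lapply(p1@biclusters, function(b) b@genes)),
    unlist(lapply(p2@biclusters, function(b) b@genes)))))
  allB <- c(p1@biclusters, p2@biclusters)
  T <- max(1L, vapply(allB, function(b) b@tEnd, 1L))
  Q <- max(1L, unlist(lapply(allB, function(b) b@profile)))
  list(genes = geneLevels, T = T, Q = Q)
}

#' Jaccard similarity between two temporal biclusters
#'
#' The intersection size is |G1 n G2| times the number of time points in the
#' window overlap at which both profiles carry the same state; bicluster
#' sizes are |G| * |window length|; the result is
#' |B1 n B2| / (|B1| + |B2| - |B1 n B2|), in [0, 1].
#'
#' @param b1,b2 \linkS4class{Bicluster} objects over the same gene universe
#'   and time axis.
#' @return Jaccard index in [0, 1].
#' @export
biclusterJaccard <- function(b1, b2) {
  gOv <- length(intersect(b1@genes, b2@genes))
  a <- max(b1@tStart, b2@tStart)
  b <- min(b1@tEnd, b2@tEnd)
  jOv <- if (a > b) 0L else
    sum(b1@profile[(a:b) - b1@tStart + 1L] == b2@profile[(a:b) - b2@tStart + 1L])
  num <- gOv * jOv
  s1 <- length(b1@genes) * (b1@tEnd - b1@tStart + 1L)
  s2 <- length(b2@genes) * (b2@tEnd - b2@tStart + 1L)
  num / (s1 + s2 - num)
}

#' Patient-level similarity of two bicluster profiles (PPISim)
#'
#' Aggregates pairwise bicluster Jaccard similarities, weighted by the
#' normalized connectivity scores. The default \code{"bestmatch"} form is the
#' symmetrized weighted best match
#' \deqn{\frac{1}{2}\Big[\sum_i w_{1i} \max_j Sim(B_{1i}, B_{2j}) +
#'       \sum_j w_{2j} \max_i Sim(B_{1i}, B_{2j})\Big],}
#' which satisfies self-similarity 1 and symmetry. \code{"doublesum"} is the
#' plain bilinear form \eqn{\sum_i \sum_j w_{1i} w_{2j} Sim(B_{1i}, B_{2j})}
#' (symmetric, but self-similarity below 1).
#'
#' A patient with zero biclusters has similarity 0 to every other patient and
#' 1 to itself.
#'
#' @param p1,p2 \linkS4class{PatientProfile} objects with normalized weights.
#' @param aggregation \code{"bestmatch"} or \code{"doublesum"}.
#' @return Similarity in [0, 1].
#' @export
patientSimilarity <- function(p1, p2, aggregation = c("bestmatch", "doublesum")) {
  aggregation <- match.arg(aggregation)
  n1 <- length(p1@biclusters); n2 <- length(p2@biclusters)
  if (n1 == 0L || n2 == 0L)
    return(if (n1 == 0L && n2 == 0L && p1@patientId == p2@patientId) 1 else 0)
  for (p in list(p1, p2))
    if (abs(sum(p@weights) - 1) > 1e-6)
      stop("profile weights are not normalized (patient ", p@patientId, ")")
  co <- .pairCoords(p1, p2)
  m1 <- .profileMats(p1, co$genes, co$T, co$Q)
  m2 <- .profileMats(p2, co$genes, co$T, co$Q)
  S <- .jaccardMatrix(m1, m2)
  if (aggregation == "bestmatch")
    (sum(m1$w * apply(S, 1L, max)) + sum(m2$w * apply(S, 2L, max))) / 2
  else
    as.numeric(m1$w %*% S %*% m2$w)
}

#' Patient-by-patient similarity kernel
#'
#' @param profiles list of \linkS4class{PatientProfile} (length >= 2).
#' @param aggregation see \code{\link{patientSimilarity}}.
#' @return A \linkS4class{SimilarityKernel}: symmetric, unit diagonal,
#'   entries in [0, 1].
#' @export
similarityMatrix <- function(profiles, aggregation = "bestmatch") {
  np <- length(profiles)
  stopifnot(np >= 2L)
  ids <- vapply(profiles, function(p) p@patientId, "")
  S <- diag(1, np)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    s <- patientSimilarity(profiles[[i]], profiles[[j]], aggregation)
    S[i, j] <- s
    S[j, i] <- s
  }
  dimnames(S) <- list(ids, ids)
  new("SimilarityKernel", sim = S)
}

#' Class-distance ratio D of a similarity kernel
#'
#' The ratio of the mean off-diagonal similarity among patients of the same
#' class (both positive and negative pairs pooled) to the mean similarity of
#' cross-class pairs. Larger D means better class separation. A zero
#' cross-class mean yields +Inf.
#'
#' @param kernel a \linkS4class{SimilarityKernel}.
#' @param labels +1/-1 labels aligned with the kernel's patients.
#' @return Numeric D >= 0 (possibly Inf).
#' @export
classDistanceRatio <- function(kernel, labels) {
  S <- kernel@sim
  stopifnot(length(labels) == nrow(S), all(labels %in% c(-1, 1)))
  if (!any(labels == 1) || !any(labels == -1))
    stop("both classes must be present")
  same <- outer(labels, labels, "==") & upper.tri(S)
  cross <- outer(labels, labels, "!=") & upper.tri(S)
  num <- mean(S[same])
  den <- mean(S[cross])
  if (den == 0) return(Inf)
  num / den
}
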