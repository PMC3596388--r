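#' Precomputed context for network-connectivity scoring
#'
#' Caches, for an interaction network, the universe size N, the degree of
#' every gene and its neighbor set, so that bicluster scoring is a pure
#' lookup.
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @return A list of class \code{ScoreContext} with components \code{N},
#'   \code{degrees} (named integer) and \code{neighbors} (named list of
#'   character vectors).
#' @export
scoreContext <- function(network) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(network@edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = network@nodes)
  deg <- igraph::degree(g)
  nbr <- igraph::as_adj_list(g)
  nbr <- lapply(nbr, function(v) names(v))
  structure(list(N = length(network@nodes), degrees = deg, neighbors = nbr),
            class = "ScoreContext")
}

#' Hypergeometric association of a gene with a bicluster gene set
#'
#' Models how surprising the number of interactions between gene i and the
#' rest of the bicluster is, given gene i's degree. With N network genes,
#' M = geneSet minus gene i (m = |M|), degree d of gene i and k observed
#' edges from gene i into M, returns the upper tail P(X >= k) for
#' X ~ Hypergeometric(population N - 1, successes m, draws d). Returns
#' exactly 1 when k = 0, including genes absent from the network or with
#' degree 0.
#'
#' @param gene gene identifier.
#' @param geneSet character vector of bicluster member genes.
#' @param context a \code{\link{scoreContext}}.
#' @return Tail probability in [0, 1].
#' @export
geneAssociationP <- function(gene, geneSet, context) {
  M <- setdiff(geneSet, gene)
  m <- length(M)
  if (m == 0L) stop("gene set is empty after removing the gene itself")
  nbr <- context$neighbors[[gene]]
  k <- if (is.null(nbr)) 0L else sum(M %in% nbr)
  if (k == 0L) return(1)
  d <- context$degrees[[gene]]
  if (m > context$N - 1L) stop("gene set exceeds the network universe")
  phyper(k - 1L, m, context$N - 1L - m, d, lower.tail = FALSE)
}

#' Raw network-connectivity preference of a bicluster (PPIScore)
#'
#' Aggregates the per-gene association tails p_i over the member genes G.
#' The default is the mean enrichment \code{mean(1 - p_i)}, which lies in
#' [0, 1) and grows when member genes are more densely interconnected than
#' chance; alternatives are one minus the geometric mean of the p_i and one
#' minus the smallest p_i.
#'
#' @param bicluster a \linkS4class{Bicluster} with >= 2 genes.
#' @param context a \code{\link{scoreContext}}.
#' @param aggregator \code{"mean1mp"}, \code{"geommean"} or \code{"minp"}.
#' @return Numeric score in [0, 1].
#' @export
ppiScoreRaw <- function(bicluster, context,
                        aggregator = c("mean1mp", "geommean", "minp")) {
  aggregator <- match.arg(aggregator)
  G <- bicluster@genes
  stopifnot(length(G) >= 2L)
  p <- vapply(G, function(g) geneAssociationP(g, G, context), 0)
  switch(aggregator,
         mean1mp = mean(1 - p),
         geommean = 1 - exp(mean(log(p))),
         minp = 1 - min(p))
}

#' Normalize bicluster scores into patient weights
#'
#' Divides the raw scores by their per-patient sum so the weights sum to 1;
#' when all raw scores are 0 (no member gene of any bicluster has an edge
#' into its bicluster) the weights fall back to uniform.
#'
#' @param profile a \linkS4class{PatientProfile} whose biclusters carry raw
#'   scores.
#' @return The profile with \code{profileWeights} normalized.
#' @export
normalizeScores <- function(profile) {
  n <- length(profile@biclusters)
  if (n == 0L) {
    profile@weights <- numeric()
    return(profile)
  }
  raw <- vapply(profile@biclusters, function(b) b@score, 0)
  s <- sum(raw)
  profile@weights <- if (s > 0) raw / s else rep(1 / n, n)
  validObject(profile)
  profile
}

#' Build scored bicluster profiles for a set of patients
#'
#' Runs maximal-bicluster extraction on each patient's state matrix, scores
#' every bicluster by its network connectivity (or uniformly when
#' \code{useNetwork = FALSE}), and normalizes the weights.
#'
#' @param states named list of \linkS4class{GeneStateMatrix}, one per patient.
#' @param network an \linkS4class{InteractionNetwork} (may be NULL when
#'   \code{useNetwork = FALSE}).
#' @param ml,mo bicluster size thresholds, see \code{\link{qlBiclustering}}.
#' @param aggregator see \code{\link{ppiScoreRaw}}.
#' @param useNetwork weight biclusters by connectivity (TRUE) or uniformly.
#' @return named list of \linkS4class{PatientProfile}.
#' @export
buildProfiles <- function(states, network = NULL, ml = 2L, mo = 2L,
                          aggregator = "mean1mp", useNetwork = TRUE) {
  ctx <- if (useNetwork) scoreContext(network)
  cache <- new.env(parent = emptyenv())  # score depends on the gene set only
  out <- lapply(names(states), function(pid) {
    bics <- qlBiclustering(states[[pid]], ml, mo)
    bics <- lapply(bics, function(b) {
      b@score <- if (!useNetwork) 1 else {
        key <- paste(b@genes, collapse = ";")
        s <- cache[[key]]
        if (is.null(s)) s <- cache[[key]] <- ppiScoreRaw(b, ctx, aggregator)
        s
      }
      b
    })
    normalizeScores(PatientProfile(pid, bics))
  })
  names(out) <- names(states)
  out
}
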