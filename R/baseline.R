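#' Threshold-based baseline discretizers
#'
#' Classical one-shot discretization methods used as references against the
#' HMM/GMM hybrid. Thresholds are computed per patient within \code{scope}:
#' \code{"all"} uses the whole patient matrix, \code{"row"} one threshold per
#' gene, \code{"col"} one per time point.
#'
#' Methods (binary unless noted): \code{average}: state 2 iff value > mean;
#' \code{midrange}: threshold (min + max)/2; \code{max_x_max}: state 2 iff
#' value >= max - (x/100) * max; \code{top_x}: state 2 for the top x% of
#' values in scope (ties broken by value order then index); \code{efp}:
#' equal-frequency partition into Q states 1..Q.
#'
#' @param dataset an \linkS4class{ExpressionDataset} (imputed).
#' @param method one of \code{"average"}, \code{"midrange"},
#'   \code{"max_x_max"}, \code{"top_x"}, \code{"efp"}.
#' @param scope \code{"all"}, \code{"row"} or \code{"col"}.
#' @param x percentage in (0, 100) for \code{max_x_max} and \code{top_x}.
#' @param Q number of states for \code{efp}.
#' @return A named list with one \linkS4class{GeneStateMatrix} per patient.
#' @export
baselineDiscretize <- function(dataset, method = c("average", "midrange",
                                                   "max_x_max", "top_x", "efp"),
                               scope = c("all", "row", "col"), x = 10, Q = 3L) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (method %in% c("max_x_max", "top_x") && (x <= 0 || x >= 100))
    stop("x must lie in (0, 100)")
  Q <- as.integer(Q)
  discretizeGroup <- function(v) {
    switch(method,
      average  = ifelse(v > mean(v), 2L, 1L),
      midrange = ifelse(v > (min(v) + max(v)) / 2, 2L, 1L),
      max_x_max = ifelse(v >= max(v) - (x / 100) * max(v), 2L, 1L),
      top_x = {
        k <- ceiling(x / 100 * length(v))
        s <- integer(length(v)) + 1L
        s[order(-v, seq_along(v))[seq_len(k)]] <- 2L
        s
      },
      efp = {
        n <- length(v)
        sizes <- rep(n %/% Q, Q) + (seq_len(Q) <= n %% Q)
        s <- integer(n)
        s[order(v, seq_along(v))] <- rep(seq_len(Q), times = sizes)
        s
      })
  }
  out <- lapply(seq_along(dataset@patientIds), function(p) {
    M <- dataset@values[p, , , drop = TRUE]
    dim(M) <- c(length(dataset@geneIds), length(dataset@timePoints))
    S <- matrix(0L, nrow(M), ncol(M))
    if (scope == "all") {
      S[] <- discretizeGroup(as.vector(M))
    } else if (scope == "row") {
      for (i in seq_len(nrow(M))) S[i, ] <- discretizeGroup(M[i, ])
    } else {
      for (j in seq_len(ncol(M))) S[, j] <- discretizeGroup(M[, j])
    }
    GeneStateMatrix(S, geneIds = dataset@geneIds,
                    timePoints = dataset@timePoints,
                    Q = if (method == "efp") Q else 2L)
  })
  names(out) <- dataset@patientIds
  out
}
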