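#' Normalize expression values
#'
#' \code{zscore_gene} standardizes each gene's present values across all
#' patients and time points to mean 0 and (population) standard deviation 1;
#' \code{zscore_patient_gene} standardizes each (patient, gene) trajectory
#' across time. Constant series map to all-zero. Missing cells are untouched.
#' The HMM initialization pools values across genes, which requires comparable
#' scales, hence \code{zscore_gene} is the pipeline default.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param mode \code{"zscore_gene"}, \code{"zscore_patient_gene"} or
#'   \code{"none"}.
#' @return A normalized \linkS4class{ExpressionDataset}.
#' @export
normalizeExpression <- function(dataset, mode = c("zscore_gene",
                                                  "zscore_patient_gene",
                                                  "none")) {
  if (!mode[1L] %in% c("zscore_gene", "zscore_patient_gene", "none"))
    stop("unknown normalization mode: ", mode[1L])
  mode <- match.arg(mode)
  if (mode == "none") return(dataset)
  v <- dataset@values
  m <- dataset@mask
  zscore <- function(x) {
    mu <- mean(x)
    s <- sqrt(mean((x - mu)^2))   # population sd; constant series -> 0
    if (s == 0) rep(0, length(x)) else (x - mu) / s
  }
  if (mode == "zscore_gene") {
    for (g in seq_along(dataset@geneIds)) {
      sel <- m[, g, ]
      x <- v[, g, ][sel]
      vg <- v[, g, ]
      vg[sel] <- zscore(x)
      v[, g, ] <- vg
    }
  } else {
    for (p in seq_along(dataset@patientIds))
      for (g in seq_along(dataset@geneIds)) {
        sel <- m[p, g, ]
        if (any(sel)) v[p, g, sel] <- zscore(v[p, g, sel])
      }
  }
  dataset@values <- v
  validObject(dataset)
  dataset
}

#' Impute missing time points from the closest neighbors
#'
#' Each missing entry of a (patient, gene) trajectory is replaced by a
#' weighted mean of the 3 present values closest in time-index distance, with
#' weights 1/|t - t_k|; with fewer than 3 present values, all present values
#' are used. Neighbors are symmetric in time; ties in "closest" are resolved
#' toward the earlier time point. Present values are never altered and the
#' returned mask is all-present.
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @return An imputed \linkS4class{ExpressionDataset} with complete mask.
#' @export
imputeMissing <- function(dataset) {
  v <- dataset@values
  m <- dataset@mask
  nt <- length(dataset@timePoints)
  for (p in seq_along(dataset@patientIds))
    for (g in seq_along(dataset@geneIds)) {
      pres <- which(m[p, g, ])
      if (length(pres) == nt) next
      if (!length(pres))
        stop(sprintf("no present values for (patient %s, gene %s)",
                     dataset@patientIds[p], dataset@geneIds[g]))
      for (t in which(!m[p, g, ])) {
        d <- abs(t - pres)
        o <- order(d, pres)               # ties: earlier time point wins
        nb <- pres[o][seq_len(min(3L, length(pres)))]
        w <- 1 / abs(t - nb)
        v[p, g, t] <- sum(w * v[p, g, nb]) / sum(w)
      }
    }
  dataset@values <- v
  dataset@mask[] <- TRUE
  validObject(dataset)
  dataset
}
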