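#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters for the pipeline with their
#' defaults. Any argument overrides the default; \code{readConfig} merges a
#' YAML file over these defaults, and CLI flags override both.
#'
#' @param normalization one of \code{"zscore_gene"}, \code{"zscore_patient_gene"},
#'   \code{"none"} (dimensionless; applied before imputation).
#' @param Q number of hidden/discrete states (default 3).
#' @param sigmaFloorFrac lower clamp for emission standard deviations, as a
#'   fraction of the pooled value standard deviation (default 1e-3).
#' @param tol relative log-likelihood improvement below which EM stops.
#' @param maxIter maximum EM iterations.
#' @param discretizer \code{"hmmgmm"} or one of the baseline methods
#'   \code{"average"}, \code{"midrange"}, \code{"max_x_max"}, \code{"top_x"},
#'   \code{"efp"}.
#' @param scope baseline threshold scope: \code{"all"}, \code{"row"},
#'   \code{"col"} (per patient matrix, per gene, per time point).
#' @param x percentage parameter for \code{max_x_max} / \code{top_x}, in
#'   (0, 100).
#' @param perPatientModel fit one HMM per patient instead of one per dataset.
#' @param ml minimum window length of a bicluster (time points).
#' @param mo minimum number of genes in a bicluster.
#' @param aggregator bicluster score aggregation over per-gene tail
#'   probabilities: \code{"mean1mp"}, \code{"geommean"}, or \code{"minp"}.
#' @param simAggregation patient similarity aggregation: \code{"bestmatch"}
#'   (weighted symmetrized best match; satisfies self-similarity 1) or
#'   \code{"doublesum"}.
#' @param K neighborhood size of the KNN gate (default 7).
#' @param C soft-margin box constraint (default 1).
#' @param Kgrid,Cgrid optional vectors; when given, K and/or C are selected by
#'   inner cross-validation on each training fold.
#' @param reps,folds cross-validation scheme (default 10 repetitions of
#'   stratified 4-fold CV).
#' @param useNetwork weight biclusters by network connectivity (TRUE) or
#'   uniformly (FALSE).
#' @param seed integer RNG seed for fold draws.
#' @return A named list of class \code{tsnetConfig}.
#' @export
tsnetConfig <- function(normalization = "zscore_gene", Q = 3L,
                        sigmaFloorFrac = 1e-3, tol = 1e-4, maxIter = 100L,
                        discretizer = "hmmgmm", scope = "all", x = 10,
                        perPatientModel = FALSE, ml = 2L, mo = 2L,
                        aggregator = "mean1mp", simAggregation = "bestmatch",
                        K = 7L, C = 1, Kgrid = NULL, Cgrid = NULL,
                        reps = 10L, folds = 4L, useNetwork = TRUE,
                        seed = 1L) {
  cfg <- list(normalization = normalization, Q = as.integer(Q),
              sigmaFloorFrac = sigmaFloorFrac, tol = tol,
              maxIter = as.integer(maxIter), discretizer = discretizer,
              scope = scope, x = x, perPatientModel = isTRUE(perPatientModel),
              ml = as.integer(ml), mo = as.integer(mo),
              aggregator = aggregator, simAggregation = simAggregation,
              K = as.integer(K), C = C, Kgrid = Kgrid, Cgrid = Cgrid,
              reps = as.integer(reps), folds = as.integer(folds),
              useNetwork = isTRUE(useNetwork), seed = as.integer(seed))
  class(cfg) <- "tsnetConfig"
  cfg
}

#' Read a YAML configuration file
#'
#' Unknown keys raise an error; known keys override \code{\link{tsnetConfig}}
#' defaults.
#'
#' @param path path to a YAML (or flat key: value) file.
#' @param ... further overrides applied after the file.
#' @return A \code{tsnetConfig} list.
#' @export
readConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(tsnetConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  vals <- utils::modifyList(vals, list(...))
  do.call(tsnetConfig, vals)
}
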