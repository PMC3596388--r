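#' Classification metrics with good responders as the positive class
#'
#' Accuracy, precision (correctly predicted good responders over all
#' predicted good responders), recall (correctly detected good responders
#' over all actual good responders) and the F-measure 2PR/(P+R). Precision,
#' recall and F are 0 by convention when their denominator is 0.
#'
#' @param truth,predicted equal-length +1/-1 vectors.
#' @return Named numeric vector \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f_measure}.
#' @export
computeMetrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == -1 & predicted == 1)
  fn <- sum(truth == 1 & predicted == -1)
  acc <- mean(truth == predicted)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = acc, precision = prec, recall = rec, f_measure = f)
}

#' Select the K most similar training patients
#'
#' Similarity ties are broken by training order, so the selection is
#' deterministic.
#'
#' @param testProfile a \linkS4class{PatientProfile}.
#' @param trainProfiles list of training \linkS4class{PatientProfile}s.
#' @param K neighborhood size, 1 <= K <= number of training patients.
#' @param aggregation see \code{\link{patientSimilarity}}.
#' @return integer indices of the K nearest training patients, most similar
#'   first.
#' @export
knnSelect <- function(testProfile, trainProfiles, K, aggregation = "bestmatch") {
  n <- length(trainProfiles)
  if (K < 1L || K > n) stop("K must lie in [1, number of training patients]")
  sims <- vapply(trainProfiles, function(tp)
    patientSimilarity(testProfile, tp, aggregation), 0)
  order(-sims, seq_len(n))[seq_len(K)]
}

#' KNN-gated SVM prediction for one test patient
#'
#' The K most similar training patients are selected first; a unanimous
#' neighborhood decides the label directly without invoking the SVM.
#' Otherwise a soft-margin SVM is trained on the neighborhood, using the
#' patient similarity among neighbors as kernel, and the test patient is
#' classified by its similarity to each neighbor.
#'
#' @param testProfile a \linkS4class{PatientProfile}.
#' @param trainProfiles list of training profiles.
#' @param trainLabels +1/-1 labels aligned with \code{trainProfiles}.
#' @param K neighborhood size.
#' @param C soft-margin box constraint.
#' @param aggregation see \code{\link{patientSimilarity}}.
#' @return Predicted label, +1 or -1 (integer).
#' @export
ppiSvmKnn <- function(testProfile, trainProfiles, trainLabels, K = 7L, C = 1,
                      aggregation = "bestmatch") {
  stopifnot(length(trainProfiles) >= 1L)
  K <- min(as.integer(K), length(trainProfiles))
  nb <- knnSelect(testProfile, trainProfiles, K, aggregation)
  labs <- as.integer(trainLabels[nb])
  if (length(unique(labs)) == 1L) return(labs[1L])
  kern <- simMatrix(similarityMatrix(trainProfiles[nb], aggregation))
  sol <- solveSvmDual(kern, labs, C)
  kernelRow <- vapply(trainProfiles[nb], function(tp)
    patientSimilarity(testProfile, tp, aggregation), 0)
  svmPredict(sol, kernelRow)
}

# Stratified fold assignment; redraws (up to 100 times) if any fold holds
# all, or none, of a class.
.drawFolds <- function(labels, k) {
  n <- length(labels)
  for (try in 1:100) {
    fold <- integer(n)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- rep(seq_len(k), length.out = length(idx))[sample.int(length(idx))]
    }
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- labels[fold != f]
      all(c(-1L, 1L) %in% tr)
    }, TRUE))
    if (ok) return(fold)
  }
  warning("could not draw folds with both classes in every training fold")
  fold
}

# Discretize every patient; the HMM is fitted on the training patients only
# and applied to everyone (test sequences decoded with the training model).
.discretizeAll <- function(ds, cfg, trainIdx) {
  if (cfg$discretizer == "hmmgmm") {
    if (cfg$perPatientModel)
      return(hmmDiscretize(ds, cfg$Q, cfg$sigmaFloorFrac, cfg$tol,
                           cfg$maxIter, perPatient = TRUE)$states)
    tr <- subsetPatients(ds, trainIdx)
    model <- emTrain(initHmm(tr, cfg$Q, sigmaFloorFrac = cfg$sigmaFloorFrac),
                     tr, maxIter = cfg$maxIter, tol = cfg$tol)
    viterbiDecode(model, ds)
  } else {
    baselineDiscretize(ds, cfg$discretizer, cfg$scope, cfg$x, cfg$Q)
  }
}

# Fast prediction path over precomputed profile mats (see .profileMats);
# numerically identical to ppiSvmKnn on the corresponding profiles.
.predictOne <- function(testMat, trainMats, trainLabels, K, C, aggregation) {
  sims <- vapply(trainMats, function(m) .simFromMats(testMat, m, aggregation), 0)
  nb <- order(-sims, seq_along(sims))[seq_len(K)]
  labs <- as.integer(trainLabels[nb])
  if (length(unique(labs)) == 1L) return(labs[1L])
  Kn <- diag(1, K)
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    s <- .simFromMats(trainMats[[nb[a]]], trainMats[[nb[b]]], aggregation)
    Kn[a, b] <- Kn[b, a] <- s
  }
  sol <- solveSvmDual(Kn, labs, C)
  svmPredict(sol, sims[nb])
}

# Inner CV selection of (K, C) on the training profiles only.
.selectParams <- function(mats, labels, cfg) {
  Kgrid <- if (is.null(cfg$Kgrid)) cfg$K else cfg$Kgrid
  Cgrid <- if (is.null(cfg$Cgrid)) cfg$C else cfg$Cgrid
  if (length(Kgrid) == 1L && length(Cgrid) == 1L)
    return(list(K = Kgrid[1L], C = Cgrid[1L]))
  fold <- .drawFolds(labels, min(cfg$folds, floor(length(labels) / 2)))
  best <- NULL
  for (K in Kgrid) for (C in Cgrid) {
    preds <- integer(length(labels))
    for (f in unique(fold)) {
      tr <- which(fold != f); te <- which(fold == f)
      for (i in te)
        preds[i] <- .predictOne(mats[[i]], mats[tr], labels[tr],
                                min(K, length(tr)), C, cfg$simAggregation)
    }
    acc <- mean(preds == labels)
    if (is.null(best) || acc > best$acc)
      best <- list(K = K, C = C, acc = acc)
  }
  best
}

# Shared fold engine. `arms` maps arm name -> useNetwork flag; all arms share
# fold draws and discretization, differing only in bicluster weighting.
.runCv <- function(ds, network, cfg, arms) {
  labels <- ds@labels
  if (!length(labels)) stop("dataset has no labels")
  preds <- lapply(arms, function(a) NULL)
  for (rep in seq_len(cfg$reps)) {
    fold <- .drawFolds(labels, cfg$folds)
    for (f in seq_len(cfg$folds)) {
      trainIdx <- which(fold != f)
      testIdx <- which(fold == f)
      if (!length(testIdx)) next
      states <- .discretizeAll(ds, cfg, trainIdx)
      T <- length(ds@timePoints)
      Qmax <- max(vapply(states, function(s) s@Q, 1L))
      for (arm in names(arms)) {
        profiles <- buildProfiles(states, network, cfg$ml, cfg$mo,
                                  cfg$aggregator, useNetwork = arms[[arm]])
        mats <- lapply(profiles, .profileMats, geneLevels = ds@geneIds,
                       T = T, Q = Qmax)
        sel <- .selectParams(mats[trainIdx], labels[trainIdx], cfg)
        p <- vapply(testIdx, function(i)
          .predictOne(mats[[i]], mats[trainIdx], labels[trainIdx],
                      min(sel$K, length(trainIdx)), sel$C,
                      cfg$simAggregation), 1L)
        preds[[arm]] <- rbind(preds[[arm]], data.frame(
          rep = rep, fold = f, patient = ds@patientIds[testIdx],
          truth = labels[testIdx], predicted = p))
      }
    }
  }
  lapply(preds, function(df) .cvReport(df, cfg))
}

.cvReport <- function(predictions, cfg) {
  perRep <- do.call(rbind, lapply(split(predictions, predictions$rep),
    function(d) {
      m <- computeMetrics(d$truth, d$predicted)
      data.frame(rep = d$rep[1L], t(m))
    }))
  rownames(perRep) <- NULL
  metrics <- c("accuracy", "precision", "recall", "f_measure")
  summ <- data.frame(metric = metrics,
                     mean = vapply(metrics, function(m) mean(perRep[[m]]), 0),
                     sd = vapply(metrics, function(m) sd(perRep[[m]]), 0))
  rownames(summ) <- NULL
  new("CvReport", predictions = predictions, perRep = perRep, summary = summ,
      settings = cfg[c("reps", "folds", "K", "C", "ml", "mo", "Q",
                       "discretizer", "useNetwork", "simAggregation",
                       "aggregator")])
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' Runs \code{reps} independent repetitions of stratified \code{folds}-fold
#' cross-validation. Within every training fold the discretization model is
#' fitted on the training patients only and applied to the test patients;
#' biclusters, network scores and similarities are then computed and each
#' test patient is classified by the KNN-gated SVM. Normalization and
#' imputation are applied once up front.
#'
#' @param dataset a labeled \linkS4class{ExpressionDataset}.
#' @param network an \linkS4class{InteractionNetwork} over the dataset genes
#'   (may be NULL when \code{config$useNetwork} is FALSE).
#' @param config a \code{\link{tsnetConfig}}.
#' @param seed RNG seed for the fold draws; defaults to \code{config$seed}.
#' @return A \linkS4class{CvReport}.
#' @export
crossValidate <- function(dataset, network, config = tsnetConfig(),
                          seed = config$seed) {
  set.seed(seed)
  ds <- imputeMissing(normalizeExpression(dataset, config$normalization))
  arm <- list(main = config$useNetwork)
  .runCv(ds, network, config, arm)$main
}

#' Network-ablation experiment on shared folds
#'
#' Runs the identical pipeline twice with shared fold draws and shared
#' discretization: once weighting biclusters by network connectivity and once
#' with uniform weights (no network integration), so that any performance
#' difference is attributable to the network alone.
#'
#' @inheritParams crossValidate
#' @return list with \linkS4class{CvReport} elements \code{ppi} and
#'   \code{noppi}.
#' @export
ablateNetwork <- function(dataset, network, config = tsnetConfig(),
                          seed = config$seed) {
  set.seed(seed)
  ds <- imputeMissing(normalizeExpression(dataset, config$normalization))
  .runCv(ds, network, config, list(ppi = TRUE, noppi = FALSE))
}

#' Early-stage evaluation over truncated time courses
#'
#' Truncates every patient to the first n measurements and reruns the full
#' cross-validation per n, mirroring prediction at an early stage of
#' treatment.
#'
#' @inheritParams crossValidate
#' @param nList integer vector of time-course lengths (each >= 3); values
#'   above the number of available time points are skipped with a warning.
#' @return named list of \linkS4class{CvReport}, one per usable n.
#' @export
earlyStageEval <- function(dataset, network, config = tsnetConfig(),
                           nList = 3:length(timePoints(dataset)),
                           seed = config$seed) {
  T <- length(dataset@timePoints)
  out <- list()
  for (n in nList) {
    if (n > T) {
      warning("skipping n = ", n, " (> available time points)")
      next
    }
    stopifnot(n >= 3L)
    dsn <- subsetPatients(dataset, seq_along(dataset@patientIds), times = n)
    out[[paste0("n", n)]] <- crossValidate(dsn, network, config, seed)
  }
  out
}
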