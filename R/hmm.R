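# Observation matrix: one row per (patient, gene) sequence, one column per
# time point. Row s = (p-1)*nGenes + g.
.obsMatrix <- function(dataset) {
  d <- dim(dataset@values)
  if (any(!dataset@mask)) stop("dataset must be imputed before HMM fitting")
  matrix(aperm(dataset@values, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

# Per-state Gaussian component densities of every observation.
# Returns list over states of (nObs x n) matrices. Densities are computed
# directly (scalar mu/sigma per component) — measurably faster than dnorm in
# the EM inner loop.
.componentDensities <- function(x, model, log = FALSE) {
  n <- ncol(model@mu)
  lapply(seq_len(model@Q), function(j) {
    out <- matrix(0, length(x), n)
    for (i in seq_len(n)) {
      z <- (x - model@mu[j, i]) / model@sigma[j, i]
      lg <- -0.5 * z * z - log(model@sigma[j, i]) - 0.9189385332046727
      out[, i] <- if (log) lg else exp(lg)
    }
    out
  })
}

# Mixture emission probabilities, nObs x Q.
.emissionProb <- function(phi, model) {
  B <- matrix(0, nrow(phi[[1L]]), model@Q)
  for (j in seq_len(model@Q)) B[, j] <- phi[[j]] %*% model@w[j, ]
  B
}

# Log emission probabilities via log-sum-exp, nObs x Q.
.emissionLogProb <- function(x, model) {
  out <- matrix(0, length(x), model@Q)
  lw <- log(model@w)
  for (j in seq_len(model@Q)) {
    L <- matrix(lw[j, ], length(x), ncol(model@mu), byrow = TRUE)
    for (i in seq_len(ncol(model@mu))) {
      z <- (x - model@mu[j, i]) / model@sigma[j, i]
      L[, i] <- L[, i] - 0.5 * z * z - log(model@sigma[j, i]) -
        0.9189385332046727
    }
    m <- apply(L, 1L, max)
    out[, j] <- m + log(rowSums(exp(L - m)))
  }
  out
}

# Permute states so that state 1 has the lowest emission mean sum_i w_ji mu_ji.
.relabelModel <- function(model) {
  ord <- order(rowSums(model@w * model@mu))
  model@pi <- model@pi[ord]
  model@A <- model@A[ord, ord, drop = FALSE]
  model@w <- model@w[ord, , drop = FALSE]
  model@mu <- model@mu[ord, , drop = FALSE]
  model@sigma <- model@sigma[ord, , drop = FALSE]
  model
}

#' Initialize the HMM/GMM hybrid model
#'
#' Initial distribution, transition rows and mixture-weight rows are uniform.
#' The pooled expression values of all genes are sorted and split into Q bins
#' of equal count (any remainder spread over the lowest bins); the component
#' mean and deviation for state j and gene i are the mean and standard
#' deviation of gene i's values falling in bin j. A gene with fewer than 2
#' values in a bin falls back to the bin's all-gene mean and to
#' \code{max(bin all-gene sd, sigmaFloor)}.
#'
#' @param dataset an imputed \linkS4class{ExpressionDataset}.
#' @param Q number of hidden states (>= 2).
#' @param sigmaFloor absolute lower clamp for emission deviations; default
#'   \code{sigmaFloorFrac} times the pooled standard deviation.
#' @param sigmaFloorFrac fraction used when \code{sigmaFloor} is NULL.
#' @return An \linkS4class{HmmGmmModel}.
#' @export
initHmm <- function(dataset, Q = 3L, sigmaFloor = NULL, sigmaFloorFrac = 1e-3) {
  Q <- as.integer(Q)
  stopifnot(Q >= 1L)
  X <- .obsMatrix(dataset)
  ng <- length(dataset@geneIds)
  geneOf <- ((seq_len(nrow(X)) - 1L) %% ng) + 1L  # row s -> gene index
  pooled <- as.vector(X)
  gene <- rep(geneOf, times = ncol(X))
  if (Q > length(unique(pooled)))
    stop("Q exceeds the number of distinct pooled expression values")
  if (is.null(sigmaFloor)) sigmaFloor <- sigmaFloorFrac * sd(pooled)
  if (!is.finite(sigmaFloor) || sigmaFloor <= 0) sigmaFloor <- 1e-8
  o <- order(pooled)
  M <- length(pooled)
  sizes <- rep(M %/% Q, Q) + (seq_len(Q) <= M %% Q)
  bin <- integer(M)
  bin[o] <- rep(seq_len(Q), times = sizes)
  mu <- sig <- matrix(0, Q, ng)
  for (j in seq_len(Q)) {
    sel <- bin == j
    allMean <- mean(pooled[sel])
    allSd <- sd(pooled[sel])
    if (is.na(allSd)) allSd <- 0
    for (i in seq_len(ng)) {
      v <- pooled[sel & gene == i]
      if (length(v) >= 2L) {
        mu[j, i] <- mean(v)
        sig[j, i] <- max(sd(v), sigmaFloor)
      } else {
        mu[j, i] <- allMean
        sig[j, i] <- max(allSd, sigmaFloor)
      }
    }
  }
  new("HmmGmmModel", Q = Q, pi = rep(1 / Q, Q),
      A = matrix(1 / Q, Q, Q), w = matrix(1 / ng, Q, ng),
      mu = mu, sigma = sig, geneIds = dataset@geneIds,
      sigmaFloor = sigmaFloor, logLik = numeric())
}

# One scaled forward-backward E-step over all sequences.
# Returns loglik, gamma ((S*T) x Q in observation order), xiSum (Q x Q),
# gamma1 (S x Q).
.eStep <- function(X, A, pi, B) {
  S <- nrow(X); T <- ncol(X); Q <- ncol(B)
  idx <- function(t) ((t - 1L) * S + 1L):(t * S)
  alpha <- vector("list", T)
  cs <- matrix(0, S, T)
  a <- B[idx(1L), , drop = FALSE] * matrix(pi, S, Q, byrow = TRUE)
  cs[, 1L] <- rowSums(a)
  alpha[[1L]] <- a / cs[, 1L]
  if (T > 1L) for (t in 2L:T) {
    a <- (alpha[[t - 1L]] %*% A) * B[idx(t), , drop = FALSE]
    cs[, t] <- rowSums(a)
    alpha[[t]] <- a / cs[, t]
  }
  loglik <- sum(log(cs))
  beta <- vector("list", T)
  beta[[T]] <- matrix(1, S, Q)
  xiSum <- matrix(0, Q, Q)
  gamma <- matrix(0, S * T, Q)
  g <- alpha[[T]] * beta[[T]]
  gamma[idx(T), ] <- g / rowSums(g)
  if (T > 1L) for (t in (T - 1L):1L) {
    bb <- (B[idx(t + 1L), , drop = FALSE] * beta[[t + 1L]]) / cs[, t + 1L]
    beta[[t]] <- bb %*% t(A)
    Z <- rowSums((alpha[[t]] %*% A) * bb)
    xiSum <- xiSum + A * crossprod(alpha[[t]], bb / Z)
    g <- alpha[[t]] * beta[[t]]
    gamma[idx(t), ] <- g / rowSums(g)
  }
  list(loglik = loglik, gamma = gamma, xiSum = xiSum,
       gamma1 = gamma[idx(1L), , drop = FALSE])
}

#' Train the HMM/GMM hybrid by the EM (Baum-Welch) algorithm
#'
#' All (patient, gene) trajectories are treated as independent observation
#' sequences sharing one parameter set. Per-component responsibilities update
#' the mixture weights, means and deviations; the gene/component pairing is
#' fixed throughout. Training stops when the relative improvement of the total
#' log-likelihood falls below \code{tol} or after \code{maxIter} iterations.
#' Deviations are clamped to the model's sigma floor. On return, states are
#' relabeled in increasing order of emission mean so that state 1 is the
#' lowest expression level; the log-likelihood trace is stored in the model.
#'
#' @param model an initialized \linkS4class{HmmGmmModel}.
#' @param dataset the imputed \linkS4class{ExpressionDataset} used for
#'   initialization.
#' @param maxIter maximum number of EM iterations (0 = no update).
#' @param tol relative log-likelihood improvement threshold.
#' @return The trained, relabeled \linkS4class{HmmGmmModel}.
#' @export
emTrain <- function(model, dataset, maxIter = 100L, tol = 1e-4) {
  X <- .obsMatrix(dataset)
  x <- as.vector(X)
  trace <- numeric()
  llPrev <- -Inf
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    phi <- .componentDensities(x, model)
    B <- .emissionProb(phi, model)
    e <- .eStep(X, model@A, model@pi, B)
    if (!is.finite(e$loglik))
      stop("non-finite log-likelihood at EM iteration ", iter)
    trace <- c(trace, e$loglik)
    if (is.finite(llPrev) &&
        (e$loglik - llPrev) / abs(llPrev) < tol) {
      llPrev <- e$loglik
      break
    }
    llPrev <- e$loglik
    # M-step
    model@pi <- colMeans(e$gamma1)
    model@pi <- model@pi / sum(model@pi)
    Anew <- e$xiSum / rowSums(e$xiSum)
    model@A <- Anew
    for (j in seq_len(model@Q)) {
      r <- e$gamma[, j] / B[, j]
      r[!is.finite(r)] <- 0
      # the column scaling by w[j, ] commutes with colSums
      base <- phi[[j]] * r
      s0 <- model@w[j, ] * colSums(base)
      base <- base * x
      s1 <- model@w[j, ] * colSums(base)
      s2 <- model@w[j, ] * colSums(base * x)
      tot <- sum(s0)
      if (tot > 0) model@w[j, ] <- s0 / tot
      ok <- s0 > 1e-12
      model@mu[j, ok] <- s1[ok] / s0[ok]
      v <- s2[ok] / s0[ok] - model@mu[j, ok]^2
      model@sigma[j, ok] <- sqrt(pmax(v, 0))
    }
    model@sigma <- pmax(model@sigma, model@sigmaFloor)
  }
  model@logLik <- trace
  model <- .relabelModel(model)
  validObject(model)
  model
}

#' Viterbi decoding of per-gene state sequences
#'
#' Computes, in log space, the maximum-probability hidden state path of each
#' (patient, gene) trajectory under the model; ties are broken toward the
#' lower state index.
#'
#' @param model a trained \linkS4class{HmmGmmModel}.
#' @param dataset an imputed \linkS4class{ExpressionDataset} with the same
#'   genes as the model.
#' @return A named list with one \linkS4class{GeneStateMatrix} per patient.
#' @export
viterbiDecode <- function(model, dataset) {
  if (!identical(model@geneIds, dataset@geneIds))
    stop("model and dataset gene sets differ")
  X <- .obsMatrix(dataset)
  S <- nrow(X); T <- ncol(X); Q <- model@Q
  logB <- .emissionLogProb(as.vector(X), model)
  idx <- function(t) ((t - 1L) * S + 1L):(t * S)
  logA <- log(model@A)
  delta <- log(model@pi)[col(matrix(0, S, Q))] + logB[idx(1L), , drop = FALSE]
  dim(delta) <- c(S, Q)
  psi <- array(1L, c(S, Q, T))
  if (T > 1L) for (t in 2L:T) {
    newDelta <- matrix(0, S, Q)
    for (k in seq_len(Q)) {
      M <- delta + matrix(logA[, k], S, Q, byrow = TRUE)
      arg <- max.col(M, ties.method = "first")
      psi[, k, t] <- arg
      newDelta[, k] <- M[cbind(seq_len(S), arg)]
    }
    delta <- newDelta + logB[idx(t), , drop = FALSE]
  }
  path <- matrix(0L, S, T)
  path[, T] <- max.col(delta, ties.method = "first")
  if (T > 1L) for (t in (T - 1L):1L)
    path[, t] <- psi[cbind(seq_len(S), path[, t + 1L], t + 1L)]
  ng <- length(dataset@geneIds)
  out <- lapply(seq_along(dataset@patientIds), function(p) {
    rows <- ((p - 1L) * ng + 1L):(p * ng)
    GeneStateMatrix(path[rows, , drop = FALSE], geneIds = dataset@geneIds,
                    timePoints = dataset@timePoints, Q = Q)
  })
  names(out) <- dataset@patientIds
  out
}

#' Discretize a dataset with the HMM/GMM hybrid
#'
#' Convenience wrapper: initialize, EM-train and Viterbi-decode. One model is
#' fitted on all patients pooled (a shared state vocabulary is needed to
#' compare biclusters across patients); set \code{perPatient = TRUE} to fit
#' one model per patient instead.
#'
#' @param dataset imputed \linkS4class{ExpressionDataset}.
#' @param Q number of states.
#' @param sigmaFloorFrac,tol,maxIter see \code{\link{initHmm}} and
#'   \code{\link{emTrain}}.
#' @param perPatient fit per-patient models.
#' @return list with elements \code{model} (or per-patient model list) and
#'   \code{states} (named list of \linkS4class{GeneStateMatrix}).
#' @export
hmmDiscretize <- function(dataset, Q = 3L, sigmaFloorFrac = 1e-3, tol = 1e-4,
                          maxIter = 100L, perPatient = FALSE) {
  if (!perPatient) {
    model <- emTrain(initHmm(dataset, Q, sigmaFloorFrac = sigmaFloorFrac),
                     dataset, maxIter = maxIter, tol = tol)
    return(list(model = model, states = viterbiDecode(model, dataset)))
  }
  out <- lapply(seq_along(dataset@patientIds), function(p) {
    ds <- subsetPatients(dataset, dataset@patientIds[p])
    model <- emTrain(initHmm(ds, Q, sigmaFloorFrac = sigmaFloorFrac), ds,
                     maxIter = maxIter, tol = tol)
    list(model = model, states = viterbiDecode(model, ds)[[1L]])
  })
  states <- lapply(out, `[[`, "states")
  names(states) <- dataset@patientIds
  list(model = lapply(out, `[[`, "model"), states = states)
}

#' Subset an ExpressionDataset by patients or time points
#'
#' @param dataset an \linkS4class{ExpressionDataset}.
#' @param patients patient ids (or indices) to keep.
#' @param times optional number of leading time points to keep.
#' @return The subsetted \linkS4class{ExpressionDataset}.
#' @export
subsetPatients <- function(dataset, patients, times = NULL) {
  if (is.character(patients)) patients <- match(patients, dataset@patientIds)
  tsel <- if (is.null(times)) seq_along(dataset@timePoints) else seq_len(times)
  ExpressionDataset(dataset@values[patients, , tsel, drop = FALSE],
                    dataset@patientIds[patients], dataset@geneIds,
                    dataset@timePoints[tsel],
                    mask = dataset@mask[patients, , tsel, drop = FALSE],
                    labels = if (length(dataset@labels))
                      dataset@labels[patients] else integer())
}
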