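#' Project a symmetric matrix to its nearest positive-semidefinite matrix
#'
#' Eigenvalues below zero are clipped to zero and the matrix reassembled and
#' re-symmetrized. The patient-similarity kernel is not guaranteed PSD, while
#' the soft-margin dual presumes a valid kernel, so this projection is applied
#' to every training kernel before solving.
#'
#' @param K symmetric numeric matrix.
#' @return The clipped PSD matrix.
#' @export
nearestPsd <- function(K) {
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (all(e$values >= 0)) return((K + t(K)) / 2)
  v <- pmax(e$values, 0)
  M <- e$vectors %*% (v * t(e$vectors))
  (M + t(M)) / 2
}

#' Solve the soft-margin SVM dual on a precomputed kernel
#'
#' Maximizes \eqn{\sum_i \alpha_i - \frac12 \sum_{ij} \alpha_i \alpha_j y_i
#' y_j K_{ij}} subject to \eqn{0 \le \alpha_i \le C} and
#' \eqn{\sum_i \alpha_i y_i = 0}, by sequential minimal optimization over
#' maximal-violating pairs. The kernel is first projected to its nearest PSD
#' matrix. The bias is the mean of \eqn{y_i - \sum_j \alpha_j y_j K_{ij}}
#' over margin vectors (0 < alpha < C); with no margin vector it is the
#' midpoint of the interval of biases consistent with the KKT conditions.
#'
#' @param K symmetric kernel among the training points.
#' @param y +1/-1 labels (both classes must be present).
#' @param C box constraint (> 0).
#' @param tol KKT violation tolerance for convergence.
#' @param maxIter maximum number of pair updates.
#' @return An \linkS4class{SvmSolution}.
#' @export
solveSvmDual <- function(K, y, C = 1, tol = 1e-10, maxIter = 100000L) {
  y <- as.integer(y)
  n <- length(y)
  stopifnot(nrow(K) == n, any(y == 1L), any(y == -1L), C > 0)
  K <- nearestPsd(K)
  alpha <- numeric(n)
  f <- numeric(n)                       # f_i = sum_j alpha_j y_j K_ij
  gap <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxIter)
      stop(sprintf("SMO did not converge within %d iterations (gap %.3g)",
                   maxIter, gap))
    # maximal violating pair over -y*grad, grad_i = y_i*f_i - 1
    G <- y * f - 1
    up <- (y == 1L & alpha < C - 1e-12) | (y == -1L & alpha > 1e-12)
    lo <- (y == -1L & alpha < C - 1e-12) | (y == 1L & alpha > 1e-12)
    v <- -y * G
    i <- which(up)[which.max(v[up])]
    j <- which(lo)[which.min(v[lo])]
    gap <- v[i] - v[j]
    if (!length(gap) || gap <= tol) break
    s <- y[i] * y[j]
    if (s == 1L) {
      L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
    } else {
      L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
    }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    Ei <- f[i] - y[i]; Ej <- f[j] - y[j]
    ajNew <- if (eta > 1e-15) {
      min(max(alpha[j] + y[j] * (Ei - Ej) / eta, L), H)
    } else {
      # flat direction: move alpha_j to the endpoint with the better objective
      dObj <- function(aj) {
        da <- aj - alpha[j]
        # change in dual objective along the feasible pair direction
        da * y[j] * (Ei - Ej) - 0.5 * eta * da * da
      }
      if (dObj(L) > dObj(H)) L else H
    }
    if (abs(ajNew - alpha[j]) < 1e-14) {
      # numerically stuck pair; treat as converged at this tolerance
      break
    }
    aiNew <- alpha[i] + s * (alpha[j] - ajNew)
    df <- (aiNew - alpha[i]) * y[i] * K[, i] + (ajNew - alpha[j]) * y[j] * K[, j]
    f <- f + df
    alpha[i] <- aiNew; alpha[j] <- ajNew
  }
  e <- y - f
  free <- alpha > 1e-8 & alpha < C - 1e-8
  if (any(free)) {
    b <- mean(e[free])
  } else {
    lower <- e[(alpha <= 1e-8 & y == 1L) | (alpha >= C - 1e-8 & y == -1L)]
    upper <- e[(alpha <= 1e-8 & y == -1L) | (alpha >= C - 1e-8 & y == 1L)]
    lowerB <- if (length(lower)) max(lower) else -Inf
    upperB <- if (length(upper)) min(upper) else Inf
    b <- if (is.finite(lowerB) && is.finite(upperB)) (lowerB + upperB) / 2
         else if (is.finite(lowerB)) lowerB else if (is.finite(upperB)) upperB
         else 0
  }
  new("SvmSolution", alphas = alpha, bias = b, labels = y, cost = C, kernel = K,
      supportIndex = which(alpha > 1e-10))
}

#' KKT residual of a dual solution
#'
#' Maximum violation over the equality constraint, box constraints and the
#' complementarity conditions (through the maximal-violating-pair gap).
#'
#' @param sol an \linkS4class{SvmSolution}.
#' @return Nonnegative scalar; ~0 at optimality.
#' @export
kktResidual <- function(sol) {
  a <- sol@alphas; y <- sol@labels; K <- sol@kernel; C <- sol@cost
  f <- as.vector(K %*% (a * y))
  G <- y * f - 1
  up <- (y == 1L & a < C - 1e-12) | (y == -1L & a > 1e-12)
  lo <- (y == -1L & a < C - 1e-12) | (y == 1L & a > 1e-12)
  v <- -y * G
  gap <- if (any(up) && any(lo)) max(v[up]) - min(v[lo]) else 0
  max(abs(sum(a * y)), max(-a, 0), max(a - C, 0), gap, 0)
}

#' Dual objective value of a solution
#'
#' @param sol an \linkS4class{SvmSolution}.
#' @return \eqn{\sum \alpha_i - \frac12 \alpha' (y y' \odot K) \alpha}.
#' @export
dualObjective <- function(sol) {
  a <- sol@alphas; y <- sol@labels
  sum(a) - 0.5 * sum((a * y) * (sol@kernel %*% (a * y)))
}

#' Predict the label of a new point from kernel values
#'
#' Evaluates \eqn{sign(\sum_{i \in SV} \alpha_i y_i K(i, P) + b)}; an exact
#' zero decision value falls back to the majority label of the training
#' points (ties to +1).
#'
#' @param sol an \linkS4class{SvmSolution}.
#' @param kernelRow similarities of the new point to each training point.
#' @return Predicted label, +1 or -1 (integer).
#' @export
svmPredict <- function(sol, kernelRow) {
  val <- sum(sol@alphas * sol@labels * kernelRow) + sol@bias
  if (val > 0) 1L else if (val < 0) -1L
  else if (sum(sol@labels) >= 0L) 1L else -1L
}
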