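# Shared fixtures and independent oracles, built in code.

# Canonical set representation of a bicluster list for set comparisons.
bicKey <- function(bics) {
  sort(vapply(bics, function(b)
    paste(b@tStart, b@tEnd, paste(sort(b@genes), collapse = ";"),
          paste(b@profile, collapse = ",")), ""))
}

randomGsm <- function(n, T, Q) {
  GeneStateMatrix(matrix(sample.int(Q, n * T, replace = TRUE), n, T), Q = Q)
}

# Dataset from a patient x gene x time array (complete unless NA).
makeDataset <- function(values, labels = integer()) {
  ExpressionDataset(values, labels = labels)
}

# One-patient dataset holding given per-gene time series (rows = genes).
seriesDataset <- function(m) {
  v <- array(NA_real_, c(1L, nrow(m), ncol(m)))
  v[1L, , ] <- m
  ExpressionDataset(v, patientIds = "P1",
                    geneIds = paste0("g", seq_len(nrow(m))),
                    timePoints = seq_len(ncol(m)))
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# population of N-1 items of which m are "successes"; draw d; P(X >= k).
enumTailOracle <- function(N, m, d, k) {
  pop <- c(rep(1L, m), rep(0L, N - 1L - m))
  if (d == 0L) return(as.numeric(k <= 0L))
  draws <- utils::combn(length(pop), d)
  mean(colSums(matrix(pop[draws], nrow = d)) >= k)
}

# Brute-force Viterbi oracle: enumerate all Q^T state paths of one sequence
# and score them with the mixture emission density computed from scratch.
viterbiOracle <- function(model, x) {
  Q <- model@Q; T <- length(x)
  emis <- function(j, v)
    log(sum(model@w[j, ] * dnorm(v, model@mu[j, ], model@sigma[j, ])))
  paths <- as.matrix(expand.grid(rep(list(seq_len(Q)), T)))
  scores <- apply(paths, 1L, function(p) {
    s <- log(model@pi[p[1L]]) + emis(p[1L], x[1L])
    if (T > 1L) for (t in 2:T)
      s <- s + log(model@A[p[t - 1L], p[t]]) + emis(p[t], x[t])
    s
  })
  list(paths = paths, scores = scores, best = max(scores))
}

# Random valid HMM/GMM model for decoding tests.
randomModel <- function(Q, n, spread = 4) {
  rdir <- function(k) { v <- rexp(k) + 0.05; v / sum(v) }
  A <- matrix(0, Q, Q); w <- matrix(0, Q, n)
  for (i in seq_len(Q)) { A[i, ] <- rdir(Q); w[i, ] <- rdir(n) }
  mu <- matrix(sort(runif(Q * n, -spread, spread)), Q, n)
  sigma <- matrix(runif(Q * n, 0.3, 1.2), Q, n)
  new("HmmGmmModel", Q = as.integer(Q), pi = rdir(Q), A = A, w = w, mu = mu,
      sigma = sigma, geneIds = paste0("g", seq_len(n)), sigmaFloor = 1e-6)
}

# Tiny two-module expression cohort with clear class separation, for fast
# classifier tests.
tinyCohort <- function(seed = 3L, noiseSd = 0.15) {
  generateDataset(nPos = 7L, nNeg = 6L, nGenes = 16L, T = 5L, Q = 2L,
                  noiseSd = noiseSd, missingRate = 0.03, nModules = 2L,
                  decoyModules = 1L, moduleSize = 4L, window = c(2L, 4L),
                  seed = seed)
}
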