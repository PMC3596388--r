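# Persistent random walk over states 1..Q: stay with probability `stay`,
# otherwise jump uniformly to another state.
.stateWalk <- function(T, Q, stay = 0.7) {
  s <- integer(T)
  s[1L] <- sample.int(Q, 1L)
  for (t in seq_len(T - 1L)) {
    s[t + 1L] <- if (runif(1) < stay || Q == 1L) s[t]
                 else sample(setdiff(seq_len(Q), s[t]), 1L)
  }
  s
}

#' Generate a stochastic-block interaction network
#'
#' Genes inside a module are connected with probability \code{pIn}; all other
#' pairs (including pairs of leftover background genes) with probability
#' \code{pOut}.
#'
#' @param geneIds character vector of gene identifiers (or an integer count).
#' @param moduleSizes integer sizes of the planted modules; genes are
#'   assigned to modules in order, the remainder is background.
#' @param pIn,pOut within/between-module edge probabilities,
#'   0 <= pOut < pIn <= 1.
#' @param seed integer RNG seed.
#' @return list with \code{network} (an \linkS4class{InteractionNetwork}) and
#'   \code{modules} (named list of module gene vectors).
#' @export
generateNetwork <- function(geneIds, moduleSizes, pIn = 0.8, pOut = 0.02,
                            seed = 1L) {
  if (is.numeric(geneIds) && length(geneIds) == 1L)
    geneIds <- sprintf("g%03d", seq_len(geneIds))
  n <- length(geneIds)
  stopifnot(sum(moduleSizes) <= n)
  if (pOut < 0 || pIn > 1 || pOut >= pIn)
    stop("edge probabilities must satisfy 0 <= pOut < pIn <= 1")
  set.seed(seed)
  member <- rep(0L, n)                  # 0 = background
  pos <- 1L
  for (m in seq_along(moduleSizes)) {
    member[pos:(pos + moduleSizes[m] - 1L)] <- m
    pos <- pos + moduleSizes[m]
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sameMod <- member[pairs[, 1L]] == member[pairs[, 2L]] & member[pairs[, 1L]] > 0L
  prob <- ifelse(sameMod, pIn, pOut)
  keep <- runif(nrow(pairs)) < prob
  edges <- cbind(geneIds[pairs[keep, 1L]], geneIds[pairs[keep, 2L]])
  modules <- split(geneIds[member > 0L], member[member > 0L])
  if (length(modules)) names(modules) <- paste0("module", seq_along(modules))
  list(network = InteractionNetwork(geneIds, edges), modules = modules)
}

#' Generate a synthetic labeled time-series cohort with known ground truth
#'
#' Emulates the shape of short clinical expression time courses: two patient
#' classes, a handful of gene modules following class-specific discrete state
#' programs, plus background genes with patient-specific state walks.
#' Discriminative modules differ between the classes inside a chosen time
#' window and their genes are wired together in the interaction network;
#' decoy modules are expression-coherent in every patient (identical program
#' in both classes) but receive no network edges at all. Expression at time t
#' is the state-indexed mean (states spaced 1 apart) plus noise; entries are
#' masked missing at \code{missingRate}.
#'
#' The default shape mirrors a 52-patient cohort: 33 positive and 19 negative
#' patients, 70 genes, 7 time points, 3 states.
#'
#' @param nPos,nNeg patients per class.
#' @param nGenes,T,Q genes, time points (>= 3), states (>= 2).
#' @param noiseSd Gaussian noise standard deviation (state means are 1 apart).
#' @param missingRate per-cell missingness probability.
#' @param nModules number of discriminative modules.
#' @param decoyModules number of decoy modules.
#' @param moduleSize genes per module.
#' @param window integer c(from, to): the time window where class programs
#'   differ.
#' @param pIn,pOut network edge probabilities (see
#'   \code{\link{generateNetwork}}); decoy genes are excluded from the
#'   network generation and added as isolated nodes.
#' @param noiseModel \code{"gaussian"} or \code{"uniform"} (model-mismatch
#'   variant with matched standard deviation).
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return list with \code{dataset} (\linkS4class{ExpressionDataset}),
#'   \code{network} (\linkS4class{InteractionNetwork}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @export
generateDataset <- function(nPos = 33L, nNeg = 19L, nGenes = 70L, T = 7L,
                            Q = 3L, noiseSd = 0.25, missingRate = 0.05,
                            nModules = 3L, decoyModules = 2L, moduleSize = 6L,
                            window = c(2L, min(5L, T)), pIn = 0.8, pOut = 0.02,
                            noiseModel = c("gaussian", "uniform"), seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(T >= 3L, Q >= 2L, noiseSd >= 0,
            (nModules + decoyModules) * moduleSize <= nGenes)
  seed <- as.integer(seed)
  set.seed(seed)
  geneIds <- sprintf("g%03d", seq_len(nGenes))
  patientIds <- sprintf("P%03d", seq_len(nPos + nNeg))
  labels <- c(rep(1L, nPos), rep(-1L, nNeg))
  win <- max(1L, window[1L]):min(T, window[2L])

  nMod <- nModules + decoyModules
  moduleGenes <- if (nMod > 0L)
    split(geneIds[seq_len(nMod * moduleSize)],
          rep(seq_len(nMod), each = moduleSize)) else list()
  names(moduleGenes) <- c(if (nModules > 0L) paste0("disc", seq_len(nModules)),
                          if (decoyModules > 0L) paste0("decoy", seq_len(decoyModules)))
  bgGenes <- if (nMod > 0L) geneIds[-seq_len(nMod * moduleSize)] else geneIds

  # class-specific state programs per module
  programs <- lapply(seq_len(nMod), function(m) {
    base <- .stateWalk(T, Q)
    if (m <= nModules) {
      alt <- base
      for (t in win) alt[t] <- sample(setdiff(seq_len(Q), base[t]), 1L)
      list(pos = alt, neg = base)
    } else {
      list(pos = base, neg = base)
    }
  })
  names(programs) <- names(moduleGenes)

  # true state paths and expression values
  np <- length(patientIds)
  vals <- array(0, c(np, nGenes, T))
  states <- vector("list", np)
  planted <- vector("list", np)
  geneModule <- rep(NA_integer_, nGenes)
  geneModule[seq_len(nMod * moduleSize)] <- rep(seq_len(nMod), each = moduleSize)
  for (p in seq_len(np)) {
    cls <- if (labels[p] == 1L) "pos" else "neg"
    S <- matrix(0L, nGenes, T)
    for (m in seq_len(nMod))
      S[which(geneModule == m), ] <-
        matrix(programs[[m]][[cls]], moduleSize, T, byrow = TRUE)
    for (g in which(is.na(geneModule))) S[g, ] <- .stateWalk(T, Q)
    noise <- if (noiseModel == "gaussian") rnorm(nGenes * T, 0, noiseSd)
             else runif(nGenes * T, -noiseSd * sqrt(3), noiseSd * sqrt(3))
    vals[p, , ] <- S + matrix(noise, nGenes, T)
    states[[p]] <- GeneStateMatrix(S, geneIds = geneIds, timePoints = seq_len(T),
                                   Q = Q)
    planted[[p]] <- lapply(names(moduleGenes), function(mn)
      Bicluster(moduleGenes[[mn]], 1L, T, programs[[mn]][[cls]]))
  }
  names(states) <- names(planted) <- patientIds

  mask <- array(runif(length(vals)) >= missingRate, dim(vals))
  for (p in seq_len(np)) for (g in seq_len(nGenes))
    if (!any(mask[p, g, ])) mask[p, g, sample.int(T, 1L)] <- TRUE
  vals[!mask] <- NA_real_

  # network over discriminative modules + background; decoys stay isolated
  netGenes <- c(unlist(moduleGenes[seq_len(nModules)], use.names = FALSE), bgGenes)
  net <- generateNetwork(netGenes, rep(moduleSize, nModules), pIn, pOut,
                         seed = seed + 1L)
  network <- InteractionNetwork(geneIds, net$network@edges)

  truth <- new("SyntheticTruth", moduleGenes = moduleGenes,
               programs = programs, states = states,
               plantedBiclusters = planted, labels = labels, seed = seed,
               params = list(nPos = nPos, nNeg = nNeg, nGenes = nGenes, T = T,
                             Q = Q, noiseSd = noiseSd,
                             missingRate = missingRate, nModules = nModules,
                             decoyModules = decoyModules,
                             moduleSize = moduleSize, window = range(win),
                             pIn = pIn, pOut = pOut, noiseModel = noiseModel))
  ds <- ExpressionDataset(vals, patientIds, geneIds, seq_len(T), mask = mask,
                          labels = labels)
  list(dataset = ds, network = network, truth = truth)
}

#' Cohort-shaped preset arguments for \code{generateDataset}
#'
#' The default study conditions used by the end-to-end benchmark: 33 + 19
#' patients, 70 genes, 7 time points, 3 states, noise 0.25 (states spaced 1
#' apart), 5\% missing cells, 3 discriminative and 2 decoy modules of 6 genes.
#'
#' @param ... overrides merged over the preset.
#' @return named list of \code{\link{generateDataset}} arguments.
#' @export
baranziniLikePreset <- function(...) {
  utils::modifyList(
    list(nPos = 33L, nNeg = 19L, nGenes = 70L, T = 7L, Q = 3L, noiseSd = 0.25,
         missingRate = 0.05, nModules = 3L, decoyModules = 2L,
         moduleSize = 6L, window = c(2L, 5L), pIn = 0.8, pOut = 0.02),
    list(...))
}

#' Generate random scored patient profiles
#'
#' Property-testing helper: random biclusters (random gene subsets, windows
#' and profiles) with random nonnegative scores, normalized into patient
#' weights.
#'
#' @param n number of profiles.
#' @param nGenes,T,Q universe shape.
#' @param maxBiclusters maximum biclusters per profile (>= 1 drawn uniformly).
#' @param seed integer RNG seed.
#' @return list of \linkS4class{PatientProfile}.
#' @export
randomPatientProfiles <- function(n, nGenes = 20L, T = 6L, Q = 3L,
                                  maxBiclusters = 5L, seed = 1L) {
  set.seed(seed)
  geneIds <- sprintf("g%03d", seq_len(nGenes))
  lapply(seq_len(n), function(i) {
    nb <- sample.int(maxBiclusters, 1L)
    bics <- lapply(seq_len(nb), function(b) {
      a <- sample.int(T, 1L)
      bEnd <- a + sample.int(T - a + 1L, 1L) - 1L
      genes <- sample(geneIds, sample(2:max(2L, nGenes %/% 2L), 1L))
      Bicluster(sort(genes), a, bEnd,
                sample.int(Q, bEnd - a + 1L, replace = TRUE),
                score = runif(1))
    })
    normalizeScores(PatientProfile(sprintf("S%03d", i), bics))
  })
}
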