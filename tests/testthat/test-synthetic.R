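test_that("generation is bit-reproducible from the seed", {
  a <- generateDataset(nPos = 5L, nNeg = 4L, nGenes = 14L, T = 5L, nModules = 2L,
                       decoyModules = 1L, moduleSize = 3L, seed = 42L)
  b <- generateDataset(nPos = 5L, nNeg = 4L, nGenes = 14L, T = 5L, nModules = 2L,
                       decoyModules = 1L, moduleSize = 3L, seed = 42L)
  expect_identical(exprValues(a$dataset), exprValues(b$dataset))
  expect_identical(missingMask(a$dataset), missingMask(b$dataset))
  expect_identical(networkEdges(a$network), networkEdges(b$network))
  c <- generateDataset(nPos = 5L, nNeg = 4L, nGenes = 14L, T = 5L, nModules = 2L,
                       decoyModules = 1L, moduleSize = 3L, seed = 43L)
  expect_false(identical(exprValues(a$dataset), exprValues(c$dataset)))
})

test_that("block-model networks respect the edge probabilities", {
  tri <- generateNetwork(8L, moduleSizes = 3L, pIn = 1, pOut = 0, seed = 1L)
  e <- networkEdges(tri$network)
  expect_identical(nrow(e), 3L)          # a closed triangle, nothing else
  expect_true(all(e %in% tri$modules$module1))

  two <- generateNetwork(10L, moduleSizes = c(4L, 4L), pIn = 0.9, pOut = 0,
                         seed = 2L)
  e2 <- networkEdges(two$network)
  mod <- rep(c(1L, 2L, 0L), c(4L, 4L, 2L))
  names(mod) <- sprintf("g%03d", 1:10)
  expect_true(all(mod[e2[, 1L]] == mod[e2[, 2L]]))

  expect_error(generateNetwork(6L, 3L, pIn = 0.2, pOut = 0.5), "probabilities")

  # pooled edge count across seeds stays in the binomial 99% band
  nIn <- choose(4, 2); nOut <- choose(8, 2) - 2 * nIn
  tot <- 0L
  for (s in 1:60)
    tot <- tot + nrow(networkEdges(
      generateNetwork(8L, c(4L, 4L), pIn = 0.6, pOut = 0.1, seed = s)$network))
  mu <- 60 * (2 * nIn * 0.6 + nOut * 0.1)
  sdv <- sqrt(60 * (2 * nIn * 0.6 * 0.4 + nOut * 0.1 * 0.9))
  expect_lt(abs(tot - mu) / sdv, 3.3)
})

test_that("noiseless data decode exactly under the generating parameters", {
  g <- generateDataset(nPos = 3L, nNeg = 3L, nGenes = 10L, T = 5L, Q = 3L,
                       noiseSd = 0, missingRate = 0, nModules = 2L,
                       decoyModules = 0L, moduleSize = 3L, seed = 7L)
  n <- length(geneIds(g$dataset))
  model <- new("HmmGmmModel", Q = 3L, pi = rep(1 / 3, 3),
               A = matrix(1 / 3, 3, 3),
               w = matrix(1 / n, 3, n),
               mu = matrix(1:3, 3, n), sigma = matrix(0.05, 3, n),
               geneIds = geneIds(g$dataset), sigmaFloor = 1e-6)
  dec <- viterbiDecode(model, g$dataset)
  for (p in patientIds(g$dataset))
    expect_identical(stateMatrix(dec[[p]]), stateMatrix(g$truth@states[[p]]))
})

test_that("planted modules appear as maximal biclusters of the true states", {
  g <- generateDataset(nPos = 4L, nNeg = 4L, nGenes = 12L, T = 6L, Q = 3L,
                       noiseSd = 0.1, missingRate = 0, nModules = 1L,
                       decoyModules = 0L, moduleSize = 5L, seed = 11L)
  planted <- g$truth@plantedBiclusters[[1L]][[1L]]
  found <- enumerateBiclustersOracle(g$truth@states[[1L]], ml = 2L, mo = 3L)
  hit <- any(vapply(found, function(b)
    all(biclusterGenes(planted) %in% biclusterGenes(b)) &&
      b@tStart == 1L && b@tEnd == 6L, TRUE))
  expect_true(hit)
})

test_that("decoy modules are isolated in the network", {
  g <- generateDataset(nPos = 4L, nNeg = 4L, nGenes = 20L, T = 5L,
                       nModules = 2L, decoyModules = 2L, moduleSize = 4L,
                       pOut = 0.3, seed = 13L)
  decoys <- unlist(g$truth@moduleGenes[c("decoy1", "decoy2")])
  e <- networkEdges(g$network)
  expect_false(any(e %in% decoys))
  expect_true(all(decoys %in% networkNodes(g$network)))
})

test_that("identical class programs leave no class signal", {
  g <- generateDataset(nPos = 4L, nNeg = 4L, nGenes = 10L, T = 5L,
                       nModules = 1L, decoyModules = 1L, moduleSize = 3L,
                       seed = 17L)
  # decoy programs are shared between classes by construction
  expect_identical(g$truth@programs$decoy1$pos, g$truth@programs$decoy1$neg)
  # discriminative programs differ inside the window
  win <- g$truth@params$window
  expect_true(all(g$truth@programs$disc1$pos[win[1]:win[2]] !=
                    g$truth@programs$disc1$neg[win[1]:win[2]]))
})

test_that("full pipeline recovers planted discriminative biclusters", {
  g <- generateDataset(nPos = 8L, nNeg = 6L, nGenes = 24L, T = 7L, Q = 3L,
                       noiseSd = 0.25, missingRate = 0.03, nModules = 2L,
                       decoyModules = 1L, moduleSize = 5L, seed = 19L)
  ds <- imputeMissing(normalizeExpression(g$dataset, "none"))
  fit <- hmmDiscretize(ds, Q = 3L)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  for (p in patientIds(ds)[c(1L, 9L)]) {       # one patient per class
    found <- qlBiclustering(fit$states[[p]], ml = 2L, mo = 3L)
    for (mn in c("disc1", "disc2")) {
      target <- g$truth@moduleGenes[[mn]]
      best <- max(vapply(found, function(b)
        jac(biclusterGenes(b), target), 0))
      expect_gte(best, 0.8)
    }
  }
})
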