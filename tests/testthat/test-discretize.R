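test_that("initialization bins pooled values and inherits uniform priors", {
  ds <- seriesDataset(matrix(c(1, 2, 3, 4), 1, 4))
  m <- initHmm(ds, Q = 2L)
  expect_equal(m@mu[, 1], c(1.5, 3.5))
  expect_equal(m@sigma[, 1], rep(sd(c(1, 2)), 2), tolerance = 1e-12)
  expect_equal(m@pi, c(0.5, 0.5))

  ds3 <- makeDataset(array(rnorm(1 * 4 * 6), c(1, 4, 6)))
  m3 <- initHmm(ds3, Q = 3L)
  expect_equal(m3@pi, rep(1 / 3, 3))
  expect_true(all(m3@A == 1 / 3))
  expect_true(all(m3@w == 1 / 4))

  same <- seriesDataset(matrix(rep(1, 4), 1, 4))
  expect_error(initHmm(same, Q = 2L), "distinct")
})

test_that("EM with zero iterations only relabels; log-likelihood never drops", {
  set.seed(11)
  ds <- makeDataset(array(rnorm(2 * 3 * 5), c(2, 3, 5)))
  m0 <- initHmm(ds, Q = 2L)
  m1 <- emTrain(m0, ds, maxIter = 0L)
  ord <- order(rowSums(m0@w * m0@mu))
  expect_equal(m1@mu, m0@mu[ord, , drop = FALSE])
  expect_equal(m1@A, m0@A[ord, ord, drop = FALSE])
  expect_identical(m1@logLik, numeric())

  for (i in 1:5) {
    ds <- makeDataset(array(rnorm(2 * 3 * 5, sd = 1 + i / 2), c(2, 3, 5)))
    m <- emTrain(initHmm(ds, Q = 2L), ds, maxIter = 25L, tol = 0)
    expect_true(all(diff(m@logLik) >= -1e-8))
  }
})

test_that("EM recovers well-separated states (means 5 sd apart)", {
  # independent per-gene state walks: data drawn from the model family itself
  g <- generateDataset(nPos = 6L, nNeg = 6L, nGenes = 12L, T = 6L, Q = 2L,
                       noiseSd = 0.2, missingRate = 0, nModules = 0L,
                       decoyModules = 0L, moduleSize = 1L, seed = 21L)
  fit <- hmmDiscretize(g$dataset, Q = 2L)
  acc <- mean(mapply(function(dec, tru) mean(stateMatrix(dec) == stateMatrix(tru)),
                     fit$states, g$truth@states))
  expect_gte(acc, 0.95)
})

test_that("Viterbi decoding matches the exhaustive path oracle", {
  set.seed(31)
  checked <- 0L
  for (i in 1:110) {
    Q <- sample(2:3, 1)
    T <- sample(2:6, 1)
    n <- sample(1:2, 1)
    model <- randomModel(Q, n)
    v <- array(rnorm(1 * n * T, sd = 3), c(1, n, T))
    ds <- makeDataset(v)
    ds@geneIds <- model@geneIds[seq_len(n)]
    dec <- viterbiDecode(model, ds)[[1L]]
    for (gi in seq_len(n)) {
      orc <- viterbiOracle(model, v[1, gi, ])
      path <- stateMatrix(dec)[gi, ]
      score <- orc$scores[which(apply(orc$paths, 1L,
                                      function(r) all(r == path)))]
      expect_equal(score, orc$best, tolerance = 1e-9)
      second <- suppressWarnings(max(orc$scores[orc$scores < orc$best - 1e-9]))
      if (is.finite(second) && orc$best - second > 1e-6) {
        expect_identical(as.integer(path),
                         as.integer(orc$paths[which.max(orc$scores), ]))
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 100L)
})

test_that("Viterbi ties break toward the lower state and Q = 1 is constant", {
  # identical emission parameters for both states: every path ties
  m <- randomModel(2, 1)
  m@pi <- c(0.5, 0.5)
  m@A <- matrix(0.5, 2, 2)
  m@mu[2, ] <- m@mu[1, ]
  m@sigma[2, ] <- m@sigma[1, ]
  m@w[2, ] <- m@w[1, ]
  ds <- makeDataset(array(rnorm(4), c(1, 1, 4)))
  ds@geneIds <- m@geneIds
  expect_true(all(stateMatrix(viterbiDecode(m, ds)[[1L]]) == 1L))

  m1 <- randomModel(1, 1)
  m1@pi <- 1; m1@A <- matrix(1, 1, 1); m1@w <- matrix(1, 1, 1)
  ds1 <- makeDataset(array(rnorm(5), c(1, 1, 5)))
  ds1@geneIds <- m1@geneIds
  expect_true(all(stateMatrix(viterbiDecode(m1, ds1)[[1L]]) == 1L))
})

test_that("disjoint emission supports make the path follow the data", {
  m <- randomModel(2, 1)
  m@mu <- matrix(c(-5, 5), 2, 1)
  m@sigma <- matrix(0.1, 2, 1)
  m@w <- matrix(1, 2, 1)
  m@A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE)
  obs <- c(-5, 5, -5, 5, 5)
  ds <- makeDataset(array(obs, c(1, 1, 5)))
  ds@geneIds <- m@geneIds
  expect_identical(as.integer(stateMatrix(viterbiDecode(m, ds)[[1L]])),
                   ifelse(obs < 0, 1L, 2L))
})

test_that("baseline discretizers reproduce their closed-form examples", {
  ds <- seriesDataset(matrix(c(1, 2, 3), 1, 3))
  st <- baselineDiscretize(ds, "average", "row")
  expect_identical(as.integer(stateMatrix(st[[1L]])), c(1L, 1L, 2L))

  ds2 <- seriesDataset(matrix(c(0, 10, 4), 1, 3))
  st2 <- baselineDiscretize(ds2, "midrange", "row")
  expect_identical(as.integer(stateMatrix(st2[[1L]])), c(1L, 2L, 1L))

  ds3 <- seriesDataset(matrix(c(1, 2, 3, 4), 1, 4))
  st3 <- baselineDiscretize(ds3, "efp", "all", Q = 2L)
  expect_identical(as.integer(stateMatrix(st3[[1L]])), c(1L, 1L, 2L, 2L))

  st4 <- baselineDiscretize(ds3, "max_x_max", "row", x = 30)
  expect_identical(as.integer(stateMatrix(st4[[1L]])), c(1L, 1L, 2L, 2L))

  st5 <- baselineDiscretize(ds3, "top_x", "row", x = 25)
  expect_identical(as.integer(stateMatrix(st5[[1L]])), c(1L, 1L, 1L, 2L))

  expect_error(baselineDiscretize(ds3, "top_x", x = 0), "0, 100")
  expect_error(baselineDiscretize(ds3, "top_x", x = 100), "0, 100")
})

test_that("whole-matrix average thresholding ignores gene order", {
  set.seed(41)
  v <- array(rnorm(1 * 5 * 4), c(1, 5, 4))
  ds <- ExpressionDataset(v, "P", paste0("g", 1:5), 1:4)
  perm <- c(3, 1, 5, 2, 4)
  dsPerm <- ExpressionDataset(v[, perm, , drop = FALSE], "P",
                              paste0("g", 1:5)[perm], 1:4)
  s1 <- stateMatrix(baselineDiscretize(ds, "average", "all")[[1L]])
  s2 <- stateMatrix(baselineDiscretize(dsPerm, "average", "all")[[1L]])
  expect_identical(unname(s1[perm, ]), unname(s2))
})
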