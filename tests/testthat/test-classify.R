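test_that("metrics follow their definitions including degenerate guards", {
  truth <- c(1, 1, 1, -1, -1)
  pred <- c(1, 1, -1, 1, -1)          # TP 2, FP 1, FN 1, TN 1
  m <- computeMetrics(truth, pred)
  expect_equal(unname(m), c(3 / 5, 2 / 3, 2 / 3, 2 / 3))

  expect_equal(unname(computeMetrics(truth, truth)), rep(1, 4))

  m0 <- computeMetrics(c(1, -1), c(-1, -1))
  expect_identical(unname(m0["precision"]), 0)
  expect_identical(unname(m0["f_measure"]), 0)
})

test_that("neighbor selection is a deterministic top-K by similarity", {
  profs <- randomPatientProfiles(12, seed = 97)
  test <- profs[[1L]]
  train <- profs[-1L]
  expect_identical(sort(knnSelect(test, train, K = 11L)), 1:11)
  expect_error(knnSelect(test, train, K = 12L), "K must lie")

  # full-sort oracle
  sims <- vapply(train, function(p) patientSimilarity(test, p), 0)
  for (K in c(1L, 3L, 7L))
    expect_identical(knnSelect(test, train, K),
                     order(-sims, seq_along(sims))[seq_len(K)])

  # an identical profile is the single nearest neighbor
  twin <- PatientProfile("twin", profileBiclusters(test), profileWeights(test))
  expect_identical(knnSelect(test, c(list(twin), train), K = 1L), 1L)
})

test_that("unanimous neighborhoods bypass the SVM; K = 1 is nearest-neighbor", {
  profs <- randomPatientProfiles(9, seed = 101)
  test <- profs[[1L]]; train <- profs[-1L]
  labsAllPos <- rep(1L, 8)
  expect_identical(ppiSvmKnn(test, train, labsAllPos, K = 5L, C = 1), 1L)
  expect_identical(ppiSvmKnn(test, train, -labsAllPos, K = 5L, C = 1), -1L)

  labs <- c(1L, -1L, 1L, -1L, 1L, -1L, 1L, -1L)
  nn <- knnSelect(test, train, 1L)
  expect_identical(ppiSvmKnn(test, train, labs, K = 1L, C = 1), labs[nn])
})

test_that("prediction is invariant to training order when similarities differ", {
  profs <- randomPatientProfiles(10, seed = 103)
  test <- profs[[1L]]; train <- profs[-1L]
  labs <- c(1L, 1L, -1L, -1L, 1L, -1L, 1L, -1L, 1L)
  sims <- vapply(train, function(p) patientSimilarity(test, p), 0)
  expect_identical(anyDuplicated(sims), 0L)
  p1 <- ppiSvmKnn(test, train, labs, K = 5L, C = 1)
  perm <- sample(9)
  p2 <- ppiSvmKnn(test, train[perm], labs[perm], K = 5L, C = 1)
  expect_identical(p1, p2)
})

test_that("cross-validation is deterministic and aces separable data", {
  g <- tinyCohort(seed = 5L)
  cfg <- tsnetConfig(reps = 2L, K = 3L)
  r1 <- crossValidate(g$dataset, g$network, cfg, seed = 13L)
  r2 <- crossValidate(g$dataset, g$network, cfg, seed = 13L)
  expect_identical(cvPredictions(r1), cvPredictions(r2))
  expect_identical(cvSummary(r1), cvSummary(r2))
  expect_gte(cvSummary(r1)$mean[cvSummary(r1)$metric == "accuracy"], 0.9)
})

test_that("ablation arms share fold assignments; edgeless networks coincide", {
  g <- tinyCohort(seed = 9L)
  cfg <- tsnetConfig(reps = 2L, K = 3L)
  ab <- ablateNetwork(g$dataset, g$network, cfg, seed = 17L)
  key <- function(r) cvPredictions(r)[, c("rep", "fold", "patient", "truth")]
  expect_identical(key(ab$ppi), key(ab$noppi))

  empty <- InteractionNetwork(geneIds(g$dataset))
  ab2 <- ablateNetwork(g$dataset, empty, cfg, seed = 17L)
  expect_identical(cvPredictions(ab2$ppi), cvPredictions(ab2$noppi))
})

test_that("early-stage evaluation at n = T reproduces the full-data report", {
  g <- tinyCohort(seed = 11L)
  cfg <- tsnetConfig(reps = 1L, K = 3L)
  full <- crossValidate(g$dataset, g$network, cfg, seed = 19L)
  es <- suppressWarnings(
    earlyStageEval(g$dataset, g$network, cfg, nList = c(5L, 9L), seed = 19L))
  expect_named(es, "n5")
  expect_identical(cvPredictions(es$n5), cvPredictions(full))
  expect_warning(
    earlyStageEval(g$dataset, g$network, cfg, nList = 9L, seed = 19L),
    "skipping")
})

test_that("inner grid selection picks parameters on the training folds only", {
  g <- tinyCohort(seed = 13L)
  cfg <- tsnetConfig(reps = 1L, Kgrid = c(1L, 3L), Cgrid = c(0.5, 1))
  r <- crossValidate(g$dataset, g$network, cfg, seed = 23L)
  expect_s4_class(r, "CvReport")
  expect_true(all(cvPredictions(r)$predicted %in% c(-1L, 1L)))
})
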