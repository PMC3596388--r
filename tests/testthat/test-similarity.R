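test_that("bicluster Jaccard matches hand-computed cases", {
  b1 <- Bicluster(c("g1", "g2"), 1L, 2L, c(1L, 1L))
  expect_identical(biclusterJaccard(b1, b1), 1)

  b2 <- Bicluster(c("g3", "g4"), 1L, 2L, c(1L, 1L))
  expect_identical(biclusterJaccard(b1, b2), 0)

  # gene overlap 1; same state only at t = 2 -> 1 / (4 + 4 - 1)
  b3 <- Bicluster(c("g2", "g3"), 2L, 3L, c(1L, 2L))
  expect_equal(biclusterJaccard(b1, b3), 1 / 7, tolerance = 1e-12)

  # bounded by the size ratio
  set.seed(61)
  for (i in 1:25) {
    p1 <- randomPatientProfiles(1, seed = i)[[1L]]
    p2 <- randomPatientProfiles(1, seed = i + 100)[[1L]]
    a <- profileBiclusters(p1)[[1L]]; b <- profileBiclusters(p2)[[1L]]
    sz <- function(x) length(x@genes) * (x@tEnd - x@tStart + 1L)
    expect_lte(biclusterJaccard(a, b),
               min(sz(a), sz(b)) / max(sz(a), sz(b)) + 1e-12)
  }
})

test_that("patient similarity: identity, symmetry and the best-match value", {
  profs <- randomPatientProfiles(50, seed = 67)
  for (p in profs)
    expect_equal(patientSimilarity(p, p), 1, tolerance = 1e-9)
  for (i in seq(1, 49, by = 2)) {
    s12 <- patientSimilarity(profs[[i]], profs[[i + 1]])
    s21 <- patientSimilarity(profs[[i + 1]], profs[[i]])
    expect_identical(s12, s21)
    expect_gte(s12, 0); expect_lte(s12, 1)
  }

  # hand-computed symmetrized best match:
  # P1 = {B_a w 1}; P2 = {B_a w .5, B_disjoint w .5} -> 0.75
  ba <- Bicluster(c("g1", "g2"), 1L, 3L, c(1L, 2L, 1L), score = 1)
  bd <- Bicluster(c("g8", "g9"), 1L, 3L, c(2L, 2L, 2L), score = 1)
  p1 <- PatientProfile("A", list(ba), 1)
  p2 <- PatientProfile("B", list(ba, bd), c(0.5, 0.5))
  expect_equal(patientSimilarity(p1, p2), 0.75, tolerance = 1e-12)

  # disjoint gene universes
  p3 <- PatientProfile("C", list(bd), 1)
  expect_identical(patientSimilarity(p1, p3), 0)

  bad <- PatientProfile("D", list(ba), 1)
  bad@weights <- 0.4
  expect_error(patientSimilarity(bad, p1), "not normalized")
})

test_that("profiles without biclusters compare as 0, and 1 to themselves", {
  e1 <- PatientProfile("E1"); e2 <- PatientProfile("E2")
  full <- randomPatientProfiles(1, seed = 3)[[1L]]
  expect_identical(patientSimilarity(e1, e1), 1)
  expect_identical(patientSimilarity(e1, e2), 0)
  expect_identical(patientSimilarity(e1, full), 0)
})

test_that("increasing the weight of the best-matching bicluster never hurts", {
  set.seed(71)
  for (i in 1:20) {
    p1 <- randomPatientProfiles(1, maxBiclusters = 4, seed = i)[[1L]]
    p2 <- randomPatientProfiles(1, maxBiclusters = 4, seed = i + 50)[[1L]]
    n1 <- length(profileBiclusters(p1))
    if (n1 < 2) next
    co <- tsnet:::.pairCoords(p1, p2)
    S <- tsnet:::.jaccardMatrix(
      tsnet:::.profileMats(p1, co$genes, co$T, co$Q),
      tsnet:::.profileMats(p2, co$genes, co$T, co$Q))
    best <- apply(S, 1, max)
    hi <- which.max(best); lo <- which.min(best)
    if (hi == lo) next
    w <- profileWeights(p1)
    eps <- min(0.5 * w[lo], 0.2)
    w2 <- w; w2[hi] <- w2[hi] + eps; w2[lo] <- w2[lo] - eps
    p1b <- PatientProfile(patientIds(p1), profileBiclusters(p1), w2)
    expect_gte(patientSimilarity(p1b, p2), patientSimilarity(p1, p2) - 1e-12)
  }
})

test_that("similarity matrix is exactly symmetric with unit diagonal", {
  profs <- randomPatientProfiles(6, seed = 73)
  K <- similarityMatrix(profs)
  S <- simMatrix(K)
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 6), tolerance = 1e-9)
  expect_true(all(S >= 0 & S <= 1 + 1e-12))

  twin <- list(profs[[1L]],
               PatientProfile("copy", profileBiclusters(profs[[1L]]),
                              profileWeights(profs[[1L]])))
  expect_equal(unname(simMatrix(similarityMatrix(twin))),
               matrix(1, 2, 2), tolerance = 1e-9)
})

test_that("class-distance ratio: block kernels and a naive oracle", {
  lab <- c(1, 1, 1, -1, -1)
  S <- matrix(0.2, 5, 5)
  S[1:3, 1:3] <- 0.8; S[4:5, 4:5] <- 0.8
  diag(S) <- 1
  dimnames(S) <- list(paste0("P", 1:5), paste0("P", 1:5))
  k <- new("SimilarityKernel", sim = S)
  expect_equal(classDistanceRatio(k, lab), 4)

  Sflat <- matrix(0.5, 5, 5); diag(Sflat) <- 1
  dimnames(Sflat) <- dimnames(S)
  expect_equal(classDistanceRatio(new("SimilarityKernel", sim = Sflat), lab), 1)

  set.seed(79)
  R <- matrix(runif(25, 0.1, 0.9), 5, 5)
  R <- (R + t(R)) / 2; diag(R) <- 1
  dimnames(R) <- dimnames(S)
  same <- cross <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    if (lab[i] == lab[j]) same <- c(same, R[i, j]) else cross <- c(cross, R[i, j])
  }
  expect_equal(classDistanceRatio(new("SimilarityKernel", sim = R), lab),
               mean(same) / mean(cross), tolerance = 1e-12)
})
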