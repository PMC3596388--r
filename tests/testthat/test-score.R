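makeNet <- function(nodes, edges) {
  InteractionNetwork(nodes, matrix(edges, ncol = 2, byrow = TRUE))
}

test_that("association tail reproduces small closed forms", {
  # N = 5, gene i with degree 2 wired to both members of M (m = 2):
  # P(X >= 2) = C(2,2) C(2,0) / C(4,2) = 1/6
  net <- makeNet(c("i", "b", "c", "d", "e"), c("i", "b", "i", "c"))
  ctx <- scoreContext(net)
  expect_equal(geneAssociationP("i", c("i", "b", "c"), ctx), 1 / 6,
               tolerance = 1e-12)

  # no edges into the bicluster -> exactly 1; absent/isolated gene -> 1
  expect_identical(geneAssociationP("d", c("d", "e"), ctx), 1)
  expect_identical(geneAssociationP("e", c("e", "b"), ctx), 1)

  # degree N-1 forces drawing all of M: tail at k = m is 1
  full <- makeNet(letters[1:4], c("a","b", "a","c", "a","d"))
  ctxF <- scoreContext(full)
  expect_equal(geneAssociationP("a", letters[1:4], ctxF), 1, tolerance = 1e-12)

  expect_error(geneAssociationP("a", "a", ctxF), "empty")
})

test_that("association tail equals the exhaustive subset oracle", {
  set.seed(53)
  cases <- 0L
  while (cases < 30L) {
    N <- sample(4:10, 1)
    nodes <- paste0("n", seq_len(N))
    pairs <- t(utils::combn(N, 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) next
    net <- InteractionNetwork(nodes, cbind(nodes[pairs[keep, 1]],
                                           nodes[pairs[keep, 2]]))
    ctx <- scoreContext(net)
    gs <- sample(nodes, sample(2:min(5, N - 1), 1))
    gene <- gs[1L]
    m <- length(gs) - 1L
    k <- sum(gs[-1L] %in% ctx$neighbors[[gene]])
    p <- geneAssociationP(gene, gs, ctx)
    pOracle <- if (k == 0L) 1 else
      enumTailOracle(N, m, unname(ctx$degrees[gene]), k)
    expect_equal(p, pOracle, tolerance = 1e-12)
    cases <- cases + 1L
  }
})

test_that("bicluster score: worked 2-gene example and degenerate zero", {
  # 9 nodes, a-b edge, both degree 1: population N-1 = 8, one success, one
  # draw -> p = C(1,1)C(7,0)/C(8,1) = 1/8 each, score 1 - 1/8
  nodes <- paste0("n", 1:9)
  edges <- rbind(c("n1", "n2"), c("n3", "n4"))   # second edge keeps n3/n4 busy
  net <- InteractionNetwork(nodes, edges)
  ctx <- scoreContext(net)
  b <- Bicluster(c("n1", "n2"), 1L, 2L, c(1L, 1L))
  expect_equal(ppiScoreRaw(b, ctx), 1 - 1 / 8, tolerance = 1e-12)

  bEdgeless <- Bicluster(c("n5", "n6"), 1L, 2L, c(1L, 1L))
  expect_identical(ppiScoreRaw(bEdgeless, ctx), 0)
})

test_that("adding an internal edge never lowers the score", {
  set.seed(59)
  nodes <- paste0("n", 1:9)
  for (i in 1:20) {
    pairs <- t(utils::combn(9, 2))
    keep <- runif(nrow(pairs)) < 0.3
    edges <- cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
    net <- InteractionNetwork(nodes, edges)
    G <- sample(nodes, 3)
    inG <- t(utils::combn(G, 2))
    have <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    missing <- inG[!(paste(pmin(inG[, 1], inG[, 2]),
                           pmax(inG[, 1], inG[, 2])) %in% have), , drop = FALSE]
    if (!nrow(missing)) next
    net2 <- InteractionNetwork(nodes, rbind(edges, missing[1L, ]))
    b <- Bicluster(G, 1L, 2L, c(1L, 1L))
    expect_gte(ppiScoreRaw(b, scoreContext(net2)),
               ppiScoreRaw(b, scoreContext(net)) - 1e-12)
  }
})

test_that("score is invariant under gene relabeling", {
  nodes <- paste0("n", 1:8)
  edges <- rbind(c("n1","n2"), c("n2","n3"), c("n1","n3"), c("n4","n5"))
  net <- InteractionNetwork(nodes, edges)
  b <- Bicluster(c("n1", "n2", "n3"), 1L, 3L, c(1L, 2L, 1L))
  # relabel: swap n1 <-> n6 everywhere
  swap <- function(x) { x[x == "n1"] <- "tmp"; x[x == "n6"] <- "n1"
                        x[x == "tmp"] <- "n6"; x }
  net2 <- InteractionNetwork(nodes, apply(edges, 2, swap))
  b2 <- Bicluster(swap(c("n1", "n2", "n3")), 1L, 3L, c(1L, 2L, 1L))
  expect_equal(ppiScoreRaw(b, scoreContext(net)),
               ppiScoreRaw(b2, scoreContext(net2)), tolerance = 1e-12)
})

test_that("weight normalization sums to one with degenerate fallbacks", {
  mk <- function(scores) {
    bics <- lapply(scores, function(s)
      Bicluster("g1", 1L, 1L, 1L, score = s))
    bics <- lapply(bics, function(b) { b@genes <- c("g1", "g2"); b })
    normalizeScores(PatientProfile("P", bics))
  }
  expect_equal(profileWeights(mk(c(1, 1, 2))), c(0.25, 0.25, 0.5))
  expect_equal(profileWeights(mk(c(0, 0))), c(0.5, 0.5))
  expect_equal(profileWeights(mk(3)), 1)
  expect_equal(sum(profileWeights(mk(runif(7)))), 1, tolerance = 1e-12)
})

test_that("clique biclusters outscore edgeless ones of the same size", {
  nodes <- paste0("n", 1:10)
  cliq <- t(utils::combn(c("n1", "n2", "n3"), 2))
  net <- InteractionNetwork(nodes, cliq)
  ctx <- scoreContext(net)
  bClique <- Bicluster(c("n1", "n2", "n3"), 1L, 2L, c(1L, 1L))
  bEmpty <- Bicluster(c("n4", "n5", "n6"), 1L, 2L, c(1L, 1L))
  expect_gt(ppiScoreRaw(bClique, ctx), ppiScoreRaw(bEmpty, ctx))
})
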