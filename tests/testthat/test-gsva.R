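test_that("kernel CDF matches a direct double-loop evaluation", {
  set.seed(10)
  x <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
  z <- kcdfTransform(x)
  expect_equal(unname(z[, ]), unname(oracleKcdf(x)), tolerance = 1e-12)
})

test_that("constant genes get z = 0.5 and two-sample z values are complementary", {
  x <- rbind(flat = c(3, 3, 3), var = c(1, 2, 5))
  colnames(x) <- paste0("S", 1:3)
  z <- suppressMessages(kcdfTransform(x))
  expect_true(all(z["flat", ] == 0.5))
  expect_equal(attr(z, "nConstantGenes"), 1L)

  x2 <- rbind(g = c(1, 4), pad = c(0, 9))
  colnames(x2) <- c("a", "b")
  z2 <- kcdfTransform(x2)
  expect_equal(z2["g", "a"] + z2["g", "b"], 1)  # kernel symmetry
})

test_that("kernel CDF rejects degenerate inputs", {
  expect_error(kcdfTransform(matrix(1:3, 3, 1)), "at least 2 samples")
  expect_error(kcdfTransform(matrix(2, 3, 4)), "constant")
})

test_that("kernel CDF is invariant to per-gene positive affine transforms", {
  set.seed(11)
  x <- matrix(rnorm(6 * 8), 6, 8,
              dimnames = list(paste0("G", 1:6), paste0("S", 1:8)))
  y <- x * 3.7 + 12  # shift and scale cancel in (x - x') / h
  expect_equal(unname(kcdfTransform(x)[, ]), unname(kcdfTransform(y)[, ]),
               tolerance = 1e-9)
})

test_that("symmetrized ranks fold about the middle of the list", {
  z <- matrix(c(0.9, 0.7, 0.4, 0.1), 4, 1,
              dimnames = list(paste0("G", 1:4), "S1"))
  rs <- rankStats(z)
  expect_equal(unname(rs$tau[, 1]), 1:4)
  expect_equal(unname(rs$r[, 1]), c(1, 0, 1, 2))  # |4/2 - tau|
})

test_that("per-sample ranks are permutations and r is reversal invariant", {
  set.seed(12)
  z <- matrix(runif(30), 10, 3)
  rownames(z) <- paste0("G", 1:10)
  rs <- rankStats(z)
  p <- nrow(z)
  for (j in 1:3)
    expect_equal(sum(rs$tau[, j]), p * (p + 1) / 2)
  rsRev <- rankStats(-z)  # reverses each sample's order
  for (j in 1:3)
    expect_equal(sort(unname(rs$r[, j])), sort(unname(rsRev$r[, j])))
})

test_that("rank ties break deterministically by input gene order", {
  z <- matrix(c(0.5, 0.5, 0.2), 3, 1,
              dimnames = list(c("A", "B", "C"), "S1"))
  rs <- rankStats(z)
  expect_equal(unname(rs$tau[, 1]), c(1, 2, 3))
})

test_that("perfect top and bottom enrichment hit the +1 / -1 limits", {
  z <- matrix(seq(1, 0, length.out = 10), 10, 1,
              dimnames = list(paste0("G", 1:10), "S1"))
  rs <- rankStats(z)
  expect_equal(enrichmentScore(rs, 1:3, 1, mode = "max_dev"), 1)
  expect_equal(enrichmentScore(rs, 8:10, 1, mode = "max_dev"), -1)
})

test_that("hand-specified six-gene walk matches the cumulative-sum oracle", {
  z <- matrix(c(0.95, 0.8, 0.6, 0.5, 0.3, 0.05), 6, 1,
              dimnames = list(paste0("G", 1:6), "S1"))
  rs <- rankStats(z)
  for (set in list(c(1L, 4L), c(2L, 6L), c(3L, 5L)))
    for (mode in c("max_diff", "max_dev"))
      expect_equal(enrichmentScore(rs, set, 1, mode = mode),
                   oracleES(z, set, 1, mode = mode), tolerance = 1e-12)
})

test_that("enrichment errors on empty or whole-matrix gene sets", {
  z <- matrix(runif(8), 4, 2, dimnames = list(paste0("G", 1:4), NULL))
  rs <- rankStats(z)
  expect_error(enrichmentScore(rs, c("NOPE"), 1), "no signature genes")
  expect_error(enrichmentScore(rs, 1:4, 1), "whole matrix")
})

test_that("score matrix has one row per signature and stays in [-1, 1]", {
  set.seed(13)
  x <- matrix(rnorm(40 * 12), 40, 12,
              dimnames = list(paste0("G", 1:40), paste0("S", 1:12)))
  sets <- lapply(1:10, function(k) sample(rownames(x), 5))
  names(sets) <- paste0("sig", 1:10)
  gs <- gsvaScores(x, sets)
  expect_equal(dim(gs), c(10L, 12L))
  expect_true(all(scoreMatrix(gs) >= -1 & scoreMatrix(gs) <= 1))
})

test_that("missing signature genes are intersected out and counted; empty sets error by name", {
  set.seed(14)
  x <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(paste0("G", 1:20), paste0("S", 1:5)))
  gs <- gsvaScores(x, list(ok = c("G1", "G2", "ZZZ")))
  expect_equal(unname(missingGenes(gs)["ok"]), 1L)
  expect_error(gsvaScores(x, list(bad = c("X", "Y"))), "bad")
})

test_that("scores are invariant to sample-independent gene reordering", {
  set.seed(15)
  x <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(paste0("G", 1:30), paste0("S", 1:6)))
  sets <- list(a = c("G3", "G7", "G11"), b = c("G20", "G25"))
  perm <- sample(nrow(x))
  s1 <- scoreMatrix(gsvaScores(x, sets))
  s2 <- scoreMatrix(gsvaScores(x[perm, ], sets))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("noise-free pure tumors score their own signature highest", {
  p <- ScSimParams(nCells = 240, nGenes = 400, kTypes = 3,
                   typeProps = rep(1 / 3, 3), markersPerType = 40,
                   markerLogFC = log(8), nAggregate = 0, seed = 16)
  sce <- normalizeCounts(simulateSingleCells(p))
  sig <- buildSignatures(
    findClusterMarkers(sce, factor(sce$trueType)), maxGenes = 100)
  prof <- typeProfilesFromCells(sce)
  bulk <- simulateBulk(
    BulkSimParams(nTumors = 30, purity = 1, noiseSD = 0,
                  subtypeRule = defaultSubtypeRule(3),
                  hazardMultipliers = rep(1, 3), seed = 17),
    prof)
  gs <- gsvaScores(SummarizedExperiment::assay(bulk), sig)
  s <- scoreMatrix(gs)
  for (j in seq_len(ncol(s))) {
    want <- paste0("cluster", bulk$trueType[j])
    expect_identical(rownames(s)[which.max(s[, j])], want)
  }
})

test_that("both walk statistics agree with the oracle on random instances", {
  set.seed(18)
  for (rep in 1:20) {
    p <- sample(10:40, 1)
    n <- sample(2:5, 1)
    x <- matrix(rnorm(p * n), p, n,
                dimnames = list(paste0("G", seq_len(p)), NULL))
    z <- kcdfTransform(x)
    rs <- rankStats(z)
    m <- sample(2:(p - 1), 1)
    set <- sample(p, m)
    j <- sample(n, 1)
    tw <- sample(c(0.5, 1, 2), 1)
    for (mode in c("max_diff", "max_dev"))
      expect_equal(enrichmentScore(rs, set, j, tauWeight = tw, mode = mode),
                   oracleES(z, set, j, tauWeight = tw, mode = mode),
                   tolerance = 1e-10)
  }
})
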