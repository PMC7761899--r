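test_that("QC removes cells strictly above the detected-gene ceiling", {
  # 3 cells detecting 4, 5 and 6 genes out of 6
  m <- Matrix::Matrix(cbind(c(1, 1, 1, 1, 0, 0),
                            c(1, 1, 1, 1, 1, 0),
                            c(1, 1, 1, 1, 1, 1)), sparse = TRUE)
  dimnames(m) <- list(paste0("G", 1:6), paste0("C", 1:3))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  kept <- qcFilter(sce, maxGenes = 5, maxMito = 1)
  expect_identical(colnames(kept), c("C1", "C2"))  # boundary cell retained
  rep <- S4Vectors::metadata(kept)$qcFilter
  expect_equal(rep$nRemovedGenes, 1)
  expect_equal(rep$nRemovedMito, 0)
})

test_that("QC removes cells strictly above the mitochondrial ceiling", {
  m <- Matrix::Matrix(rbind(c(10, 11, 30), c(90, 89, 70)), sparse = TRUE)
  dimnames(m) <- list(c("MT-G01", "G2"), paste0("C", 1:3))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  kept <- qcFilter(sce, maxGenes = 6500, maxMito = 0.1)
  # fractions: 0.10 (boundary, kept), 0.11, 0.30
  expect_identical(colnames(kept), "C1")
  expect_equal(S4Vectors::metadata(kept)$qcFilter$nRemovedMito, 2)
})

test_that("a matrix without mitochondrial genes has zero mito fractions", {
  m <- Matrix::Matrix(matrix(rpois(20, 4), 4, 5), sparse = TRUE)
  dimnames(m) <- list(paste0("G", 1:4), paste0("C", 1:5))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  expect_true(all(perCellQC(sce)$mitoFrac == 0))
  expect_equal(ncol(qcFilter(sce, maxGenes = 10, maxMito = 0)), 5)
})

test_that("QC is idempotent and counts violations correctly on simulated data", {
  p <- ScSimParams(nCells = 500, nGenes = 400, kTypes = 2,
                   typeProps = c(0.5, 0.5), markersPerType = 20,
                   nAggregate = 25, seed = 8)
  sce <- simulateSingleCells(p)
  qc <- perCellQC(sce)
  maxGenes <- sort(qc$detected, decreasing = TRUE)[8] # exactly 7 above
  expected <- sum(qc$detected > maxGenes | qc$mitoFrac > 0.12)
  f1 <- qcFilter(sce, maxGenes = maxGenes, maxMito = 0.12)
  expect_equal(ncol(f1), ncol(sce) - expected)
  f2 <- qcFilter(f1, maxGenes = maxGenes, maxMito = 0.12)
  expect_identical(colnames(f2), colnames(f1))
})

test_that("QC erroring out when nothing survives advises threshold review", {
  m <- Matrix::Matrix(matrix(1, 3, 2), sparse = TRUE)
  dimnames(m) <- list(paste0("G", 1:3), c("C1", "C2"))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  expect_error(qcFilter(sce, maxGenes = 1, maxMito = 1), "threshold")
})

test_that("normalization matches its closed form", {
  counts <- Matrix::Matrix(cbind(c(1, 9999, 0), c(2, 2, 6)), sparse = TRUE)
  dimnames(counts) <- list(paste0("G", 1:3), c("C1", "C2"))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = counts))
  norm <- SummarizedExperiment::assay(normalizeCounts(sce), "logcounts")
  # cell with total 10,000 and count 1 -> ln 2
  expect_equal(norm[1, 1], log(2), tolerance = 1e-12)
  expect_equal(norm[3, 1], 0)  # zero count stays zero
  expect_equal(norm[1, 2], log1p(2 / 10 * 1e4))
})

test_that("normalization is invariant to within-cell scaling and invertible", {
  m <- makeBlockMatrix()
  sceA <- SingleCellExperiment::SingleCellExperiment(
    list(counts = Matrix::Matrix(m, sparse = TRUE)))
  m2 <- m; m2[, 1] <- m2[, 1] * 2  # double every count in one cell
  sceB <- SingleCellExperiment::SingleCellExperiment(
    list(counts = Matrix::Matrix(m2, sparse = TRUE)))
  a <- SummarizedExperiment::assay(normalizeCounts(sceA), "logcounts")
  b <- SummarizedExperiment::assay(normalizeCounts(sceB), "logcounts")
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-12)
  # expm1 then rescale recovers the within-cell fractions exactly
  frac <- as.matrix(expm1(a)) / 1e4
  expect_equal(frac, t(t(m) / colSums(m)), tolerance = 1e-10)
})

test_that("normalization refuses zero-total cells", {
  m <- Matrix::Matrix(cbind(c(1, 2), c(0, 0)), sparse = TRUE)
  dimnames(m) <- list(c("G1", "G2"), c("C1", "C2"))
  sce <- SingleCellExperiment::SingleCellExperiment(list(counts = m))
  expect_error(normalizeCounts(sce), "zero total")
})

test_that("PCA concentrates a single direction of variance in PC1", {
  set.seed(1)
  n <- 40
  t <- rnorm(n)
  x <- outer(rnorm(25), t)  # rank-1 structure
  dimnames(x) <- list(paste0("G", 1:25), paste0("C", 1:n))
  emb <- pcaEmbed(x, nPcs = 3, nHvg = 25)
  ve <- attr(emb, "varExplained")
  expect_gt(ve[1], 0.99)
  expect_lt(ve[2], 0.01)
})

test_that("the explained-variance spectrum is rotation invariant", {
  set.seed(2)
  x <- matrix(rnorm(30 * 50), 30, 50)
  dimnames(x) <- list(paste0("G", 1:30), paste0("C", 1:50))
  q <- qr.Q(qr(matrix(rnorm(900), 30, 30)))
  y <- q %*% x
  dimnames(y) <- dimnames(x)
  # same gene universe, no HVG subsetting, covariance PCA
  ve1 <- attr(pcaEmbed(x, nPcs = 5, nHvg = 30, scaleGenes = FALSE),
              "varExplained")
  ve2 <- attr(pcaEmbed(y, nPcs = 5, nHvg = 30, scaleGenes = FALSE),
              "varExplained")
  expect_equal(ve1, ve2, tolerance = 1e-8)
  expect_error(pcaEmbed(x, nPcs = 31), "nPcs")
})

test_that("PCA is deterministic with a fixed sign convention", {
  m <- makeBlockMatrix(nGenesPerBlock = 10, nCellsPerBlock = 15)
  e1 <- pcaEmbed(m, nPcs = 4, nHvg = 20)
  e2 <- pcaEmbed(m, nPcs = 4, nHvg = 20)
  expect_identical(e1, e2)
})

test_that("PCA separates well-separated simulated types", {
  p <- ScSimParams(nCells = 300, nGenes = 600, kTypes = 3,
                   typeProps = rep(1 / 3, 3), markersPerType = 40,
                   markerLogFC = log(8), nAggregate = 0, seed = 21)
  sce <- normalizeCounts(simulateSingleCells(p))
  emb <- pcaEmbed(sce, nPcs = 10, nHvg = 300)
  # silhouette of the true labels on the first two PCs
  lab <- as.integer(factor(sce$trueType))
  d <- as.matrix(dist(emb[, 1:2]))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("SNN clustering resolves two separated clouds exactly", {
  set.seed(7)
  emb <- rbind(matrix(rnorm(60 * 5), 60, 5),
               matrix(rnorm(60 * 5, mean = 30), 60, 5))
  rownames(emb) <- paste0("C", 1:120)
  # equal-sized clouds: the size tie during relabeling must be announced
  expect_warning(
    cl <- snnCluster(emb, kNeighbors = 15, resolution = 0.3, seed = 1),
    "tie")
  truth <- rep(c(1, 2), each = 60)
  expect_equal(nlevels(droplevels(cl)), 2)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)
})

test_that("one homogeneous cloud stays one cluster at low resolution", {
  set.seed(8)
  emb <- matrix(rnorm(80 * 5), 80, 5)
  rownames(emb) <- paste0("C", 1:80)
  cl <- snnCluster(emb, kNeighbors = 20, resolution = 0.1, seed = 1)
  expect_equal(nlevels(droplevels(cl)), 1)
})

test_that("cluster labels are size-ordered and the report is Table-1-shaped", {
  set.seed(9)
  emb <- rbind(matrix(rnorm(90 * 4), 90, 4),
               matrix(rnorm(40 * 4, 25), 40, 4),
               matrix(rnorm(15 * 4, -25), 15, 4))
  rownames(emb) <- paste0("C", 1:145)
  cl <- snnCluster(emb, kNeighbors = 10, resolution = 0.3, seed = 1)
  tab <- clusterSummaryTable(cl)
  expect_identical(tab$cluster, as.character(seq_len(nrow(tab)) - 1))
  expect_true(all(diff(tab$nCells) <= 0))        # largest first
  expect_equal(sum(tab$nCells), 145)
  expect_lt(abs(sum(tab$percent) - 100), 0.2)    # rounded percents
  # relabeling is a pure permutation: contents preserved
  expect_equal(sort(as.integer(table(cl))), sort(c(90, 40, 15)))
  expect_error(snnCluster(emb, kNeighbors = 145), "smaller")
})
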