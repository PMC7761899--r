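#' Per-cell QC statistics
#'
#' Computes, per cell: total UMI count, number of detected genes
#' (nonzero counts), and the fraction of counts on mitochondrial genes
#' (identified by a symbol prefix; gene lists differ between references,
#' so the prefix is configurable).
#'
#' @param sce SingleCellExperiment with a \code{counts} assay
#' @param mitoPrefix gene-symbol prefix marking mitochondrial genes
#' @return data.frame with columns \code{total}, \code{detected},
#'   \code{mitoFrac}
#' @export
perCellQC <- function(sce, mitoPrefix = "MT-") {
  counts <- SummarizedExperiment::assay(sce, "counts")
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  isMito <- startsWith(rownames(counts), mitoPrefix)
  mitoFrac <- if (any(isMito))
    Matrix::colSums(counts[isMito, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  data.frame(total = total, detected = detected, mitoFrac = mitoFrac,
             row.names = colnames(counts))
}

#' Filter low-quality cells
#'
#' Removes probable cell aggregates (more than \code{maxGenes} detected
#' genes) and probable dead cells (mitochondrial fraction above
#' \code{maxMito}). Both thresholds are strict: a cell at exactly the
#' boundary is retained. Idempotent.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay
#' @param maxGenes detected-gene ceiling (default 6500)
#' @param maxMito mitochondrial-fraction ceiling (default 0.1)
#' @param mitoPrefix mitochondrial gene-symbol prefix
#' @return the filtered SingleCellExperiment; \code{metadata(sce)$qcFilter}
#'   records how many cells each rule removed
#' @export
qcFilter <- function(sce, maxGenes = 6500, maxMito = 0.1,
                     mitoPrefix = "MT-") {
  qc <- perCellQC(sce, mitoPrefix)
  byGenes <- qc$detected > maxGenes
  byMito <- qc$mitoFrac > maxMito
  keep <- !(byGenes | byMito)
  if (!any(keep))
    stop("all cells removed by QC; review maxGenes/maxMito thresholds")
  out <- sce[, keep]
  S4Vectors::metadata(out)$qcFilter <- list(
    nRemovedGenes = sum(byGenes), nRemovedMito = sum(byMito),
    nRemoved = sum(!keep), nKept = sum(keep),
    maxGenes = maxGenes, maxMito = maxMito)
  out
}

#' Library-size normalization with log transform
#'
#' Divides each cell's counts by its total, multiplies by
#' \code{scaleFactor} (10,000), and applies \code{log(1 + .)}. Zero counts
#' map to zero; doubling every count in a cell leaves its normalized
#' profile unchanged.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay
#' @param scaleFactor counts-per-X scale (default 1e4)
#' @return the SingleCellExperiment with a sparse \code{logcounts} assay
#'   added
#' @export
normalizeCounts <- function(sce, scaleFactor = 1e4) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  total <- Matrix::colSums(counts)
  if (any(total == 0))
    stop(sum(total == 0), " cell(s) with zero total counts; run qcFilter ",
         "or drop empty columns first")
  norm <- counts %*% Matrix::Diagonal(x = scaleFactor / total)
  norm@x <- log1p(norm@x)  # sparse-safe: log1p(0) = 0
  dimnames(norm) <- dimnames(counts)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

# Highly variable genes by binned dispersion: dispersion = var/mean of
# logcounts, z-scored within 20 bins of mean expression, top nHvg taken.
# The dispersion criterion presumes nonnegative expression; for general
# real-valued input (already-centered matrices), rank by variance instead.
selectHvg <- function(logcounts, nHvg) {
  mu <- Matrix::rowMeans(logcounts)
  m2 <- Matrix::rowMeans(logcounts^2)
  v <- pmax(m2 - mu^2, 0) * ncol(logcounts) / max(ncol(logcounts) - 1, 1)
  if (min(logcounts) < 0) {
    ord <- order(v, decreasing = TRUE)
    return(ord[seq_len(min(nHvg, length(ord)))])
  }
  ok <- mu > 0
  disp <- rep(NA_real_, length(mu))
  disp[ok] <- v[ok] / mu[ok]
  bins <- cut(mu[ok], breaks = 20)
  z <- disp[ok]
  for (b in levels(bins)) {
    i <- which(bins == b)
    if (length(i) > 1 && stats::sd(z[i]) > 0)
      z[i] <- (z[i] - mean(z[i])) / stats::sd(z[i])
    else z[i] <- 0
  }
  cand <- which(ok)[order(z, decreasing = TRUE)]
  cand[seq_len(min(nHvg, length(cand)))]
}

#' PCA embedding of normalized cells
#'
#' Selects \code{nHvg} highly variable genes by a binned dispersion-vs-mean
#' criterion on the log-normalized matrix, centers and scales each gene
#' (scaled values clipped at 10 to bound outlier leverage), and returns the
#' first \code{nPcs} principal-component coordinates of the cells. Columns
#' are ordered by decreasing explained variance; each component's sign is
#' fixed so its largest-magnitude gene loading is positive, making the
#' embedding deterministic.
#'
#' @param sce SingleCellExperiment with \code{logcounts} (or a dense/sparse
#'   genes x cells matrix)
#' @param nPcs number of components (default 10)
#' @param nHvg number of variable genes (default 2000)
#' @param scaleGenes scale each gene to unit variance before the
#'   decomposition (default TRUE, the scRNA-seq convention; set FALSE for
#'   plain covariance PCA, whose variance spectrum is invariant to
#'   orthogonal rotations of the input)
#' @return cells x nPcs matrix; attribute \code{"varExplained"} holds the
#'   per-component variance fractions, \code{"hvg"} the selected genes
#' @export
pcaEmbed <- function(sce, nPcs = 10, nHvg = 2000, scaleGenes = TRUE) {
  logcounts <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  if (nPcs > min(dim(logcounts)))
    stop("nPcs exceeds matrix dimensions")
  hvg <- selectHvg(logcounts, nHvg)
  x <- t(as.matrix(logcounts[hvg, , drop = FALSE]))  # cells x genes
  x <- scale(x, center = TRUE, scale = scaleGenes)
  x[is.na(x)] <- 0
  if (scaleGenes) {
    x[x > 10] <- 10
    x[x < -10] <- -10
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = nPcs)
  emb <- pc$x[, seq_len(nPcs), drop = FALSE]
  for (j in seq_len(nPcs)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(logcounts)
  attr(emb, "varExplained") <- pc$sdev^2 / sum(pc$sdev^2)
  attr(emb, "hvg") <- rownames(logcounts)[hvg]
  emb
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on the PCA embedding (Euclidean),
#' weights each edge by the Jaccard overlap of the two cells' neighbor
#' sets, prunes weights below \code{pruneBelow}, and runs Louvain
#' modularity optimization at the given \code{resolution}. Cluster labels
#' are integers \code{0..K-1} renumbered by decreasing cluster size; ties
#' in size are broken by the original community id (with a warning).
#'
#' @param embedding cells x dims matrix from [pcaEmbed()]
#' @param kNeighbors neighbors per cell (default 20)
#' @param resolution Louvain resolution (default 0.8)
#' @param pruneBelow discard SNN edges with Jaccard weight below this
#'   (default 1/15)
#' @param seed seed for the Louvain vertex ordering
#' @return factor of cluster labels (levels "0".."K-1"), named by cell
#' @export
snnCluster <- function(embedding, kNeighbors = 20, resolution = 0.8,
                       pruneBelow = 1 / 15, seed = 0) {
  n <- nrow(embedding)
  if (kNeighbors >= n)
    stop("kNeighbors must be smaller than the number of cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(kNeighbors)]))

  # SNN edges among kNN pairs, weight = Jaccard of neighbor sets
  nnSets <- lapply(seq_len(n), function(i) nn[i, ])
  ei <- rep(seq_len(n), each = kNeighbors)
  ej <- as.integer(t(nn))
  keep <- ei < ej
  pairs <- unique(cbind(pmin(ei, ej), pmax(ei, ej)))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nnSets[[pairs[r, 1]]]
    b <- nnSets[[pairs[r, 2]]]
    inter <- length(intersect(a, b))
    inter / (2 * kNeighbors - inter)
  }, numeric(1))
  sel <- w >= pruneBelow
  g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[sel]

  comm <- withSeed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  if (anyDuplicated(as.integer(sizes)) &&
      any(duplicated(as.integer(sizes))))
    warning("cluster-size tie during relabeling; broken by community id")
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes) - 1L
  out <- factor(relabel[memb], levels = seq_along(sizes) - 1L)
  names(out) <- rownames(embedding)
  out
}

#' Cluster size summary table
#'
#' Cluster, cell count, and percentage of total (one decimal, half-up
#' rounding), largest cluster first — the shape of a published cluster
#' distribution table.
#'
#' @param clusters factor from [snnCluster()]
#' @return data.frame with columns \code{cluster}, \code{nCells},
#'   \code{percent}
#' @export
clusterSummaryTable <- function(clusters) {
  tab <- table(clusters)
  data.frame(cluster = names(tab),
             nCells = as.integer(tab),
             percent = roundHalfUp(100 * as.integer(tab) / sum(tab), 1),
             row.names = NULL)
}

#' Two-dimensional embedding for figures
#'
#' Convenience accessor returning the first two PCA coordinates; used for
#' plotting only — no pipeline logic depends on it.
#'
#' @param embedding matrix from [pcaEmbed()]
#' @return cells x 2 matrix
#' @export
embed2d <- function(embedding) embedding[, 1:2, drop = FALSE]
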