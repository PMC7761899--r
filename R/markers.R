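# Two-sided Wilcoxon rank-sum p-value with mid-rank tie handling.
# Small groups (both sizes <= exactMax) use the exact conditional
# permutation distribution of the rank sum, enumerated over group-1
# index sets; larger groups use the normal approximation with
# tie-corrected variance and continuity correction. The exact path keeps
# tiny-cluster p-values honest where the normal approximation is off by
# far more than its nominal accuracy.
wilcoxonP <- function(x, inGroup, exactMax = 8L) {
  n1 <- sum(inGroup)
  n2 <- sum(!inGroup)
  r <- rank(x)
  n <- n1 + n2
  if (n1 <= exactMax && n2 <= exactMax) {
    obs <- sum(r[inGroup])
    sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
    return(min(1, 2 * min(mean(sums <= obs), mean(sums >= obs))))
  }
  U <- sum(r[inGroup]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tieAdj <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tieAdj / (n * (n - 1)))
  if (v <= 0) return(1)
  z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(v)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

# average natural-log fold change on de-logged means with pseudocount 1
avgLogFCStat <- function(xIn, xOut) {
  log((mean(expm1(xIn)) + 1) / (mean(expm1(xOut)) + 1))
}

#' One-vs-rest Wilcoxon marker statistics per cluster
#'
#' For every gene and every cluster (or a single requested cluster),
#' compares normalized expression in the cluster's cells against all other
#' cells with a two-sided Wilcoxon rank-sum test (mid-rank tie handling;
#' exact enumeration when both groups have at most 8 cells, otherwise the
#' tie-corrected normal approximation with continuity correction) and
#' reports the average log fold change
#' \code{ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))} together
#' with detection fractions. P-values are Bonferroni-adjusted across genes
#' within each cluster.
#'
#' @param sce SingleCellExperiment with \code{logcounts}, or a genes x
#'   cells matrix of normalized log expression
#' @param clusters factor of cluster labels per cell
#' @param cluster optional single cluster label; default all clusters
#' @param minPct optional detection-fraction prefilter (genes kept if
#'   detected in at least this fraction of either group); default 0 = none
#' @return data.frame with columns \code{gene}, \code{cluster},
#'   \code{avgLogFC}, \code{pValue}, \code{adjP}, \code{pctIn},
#'   \code{pctOut}
#' @export
findClusterMarkers <- function(sce, clusters, cluster = NULL, minPct = 0) {
  m <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  clusters <- as.factor(clusters)
  if (ncol(m) != length(clusters))
    stop("clusters length must match the number of cells")
  labs <- if (is.null(cluster)) levels(clusters) else as.character(cluster)
  res <- lapply(labs, function(cl) {
    inGroup <- clusters == cl
    if (!any(inGroup) || all(inGroup))
      stop("cluster '", cl, "' is empty or covers all cells")
    if (sum(inGroup) == 1)
      warning("cluster '", cl, "' has a single cell; statistics are ",
              "low-powered")
    xm <- as.matrix(m)
    pctIn <- rowMeans(xm[, inGroup, drop = FALSE] > 0)
    pctOut <- rowMeans(xm[, !inGroup, drop = FALSE] > 0)
    genes <- seq_len(nrow(xm))
    if (minPct > 0)
      genes <- which(pctIn >= minPct | pctOut >= minPct)
    p <- vapply(genes, function(i) wilcoxonP(xm[i, ], inGroup), numeric(1))
    lfc <- vapply(genes, function(i)
      avgLogFCStat(xm[i, inGroup], xm[i, !inGroup]), numeric(1))
    data.frame(gene = rownames(xm)[genes], cluster = cl,
               avgLogFC = lfc, pValue = p,
               adjP = stats::p.adjust(p, method = "bonferroni"),
               pctIn = pctIn[genes], pctOut = pctOut[genes],
               row.names = NULL)
  })
  do.call(rbind, res)
}

#' Build top-N cluster signatures from marker statistics
#'
#' Per cluster: keep genes with adjusted p below \code{alpha} and positive
#' average log fold change, sort by decreasing fold change (ties broken by
#' ascending p, then gene symbol), and truncate at \code{maxGenes} (100).
#' Clusters with no significant positive markers yield an empty set and a
#' warning rather than being dropped.
#'
#' @param stats marker table from [findClusterMarkers()]
#' @param maxGenes signature size cap (default 100)
#' @param alpha adjusted-p significance threshold (default 0.05)
#' @return a [SignatureCollection], one set per cluster, named
#'   \code{cluster<label>}
#' @export
buildSignatures <- function(stats, maxGenes = 100, alpha = 0.05) {
  stopifnot(all(c("gene", "cluster", "avgLogFC", "adjP") %in% names(stats)))
  labs <- unique(stats$cluster)
  sets <- lapply(labs, function(cl) {
    s <- stats[stats$cluster == cl & stats$adjP < alpha &
                 stats$avgLogFC > 0, , drop = FALSE]
    if (nrow(s) == 0) {
      warning("cluster '", cl, "': no significant positive markers; ",
              "signature is empty")
      return(character(0))
    }
    s <- s[order(-s$avgLogFC, s$pValue, s$gene), , drop = FALSE]
    utils::head(s$gene, maxGenes)
  })
  names(sets) <- paste0("cluster", labs)
  SignatureCollection(sets, stats = stats)
}
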