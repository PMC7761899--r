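#' Per-cluster expression summary for one gene
#'
#' Mean, standard deviation, median and detection fraction of a gene's
#' normalized expression within each cluster, with a shading flag for
#' clusters whose mean exceeds \code{shadeThreshold} (the ">0.1 of
#' normalized expression" convention of published relative-expression
#' tables). Values are reported on the normalized-log scale of the input;
#' the transform behind any particular published table is a reporting
#' choice, so the scale is declared rather than guessed.
#'
#' @param sce SingleCellExperiment with \code{logcounts}, or genes x cells
#'   matrix
#' @param clusters factor of cluster labels per cell
#' @param gene gene symbol
#' @param shadeThreshold mean-expression flag threshold (default 0.1)
#' @return data.frame per cluster: \code{cluster}, \code{mean}, \code{sd},
#'   \code{median}, \code{fracDetected}, \code{shaded}
#' @export
clusterGeneSummary <- function(sce, clusters, gene, shadeThreshold = 0.1) {
  m <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  if (!gene %in% rownames(m)) {
    near <- utils::head(agrep(gene, rownames(m), value = TRUE,
                              ignore.case = TRUE), 5)
    stop("gene '", gene, "' not found",
         if (length(near)) paste0("; near matches: ",
                                  paste(near, collapse = ", ")) else "")
  }
  x <- as.numeric(m[gene, ])
  clusters <- as.factor(clusters)
  res <- lapply(levels(clusters), function(cl) {
    v <- x[clusters == cl]
    data.frame(cluster = cl, mean = mean(v), sd = stats::sd(v),
               median = stats::median(v), fracDetected = mean(v > 0))
  })
  out <- do.call(rbind, res)
  out$sd[is.na(out$sd)] <- 0
  out$shaded <- out$mean > shadeThreshold
  out
}

#' Fold ratio between two expression values
#'
#' \code{a / b}, rounded half-up to one decimal — the convention for
#' printed fold comparisons ("2.7-fold higher"). A zero denominator is an
#' error; such a comparison should be reported as exclusive expression,
#' not a ratio.
#'
#' @param a,b nonnegative values, \code{b > 0}
#' @return the ratio rounded to one decimal
#' @examples
#' foldRatio(1.15, 0.42)  # 2.7
#' foldRatio(1.15, 0.12)  # 9.6
#' @export
foldRatio <- function(a, b) {
  if (any(b <= 0))
    stop("denominator is zero or negative: report exclusive expression ",
         "instead of a fold ratio")
  roundHalfUp(a / b, 1)
}

# pre-rounding ratio, used by the reciprocity property test
foldRatioRaw <- function(a, b) {
  if (any(b <= 0)) stop("denominator must be positive")
  a / b
}

#' Per-cluster expressed-gene sets and their Venn partition
#'
#' A gene counts as expressed in a cluster when it is detected (nonzero)
#' in at least \code{minFrac} of that cluster's cells. Returns each
#' cluster's expressed set plus the full partition into the
#' \code{2^m - 1} Venn regions of the m clusters: disjoint sets whose
#' union is every input gene detected anywhere.
#'
#' @param sce SingleCellExperiment with \code{logcounts}, or genes x cells
#'   matrix
#' @param clusters factor of cluster labels per cell
#' @param genes character vector of genes to partition (nonempty)
#' @param minFrac detection-fraction threshold (default 0.1)
#' @param whichClusters cluster labels to compare (default all)
#' @return list with \code{sets} (per-cluster expressed genes) and
#'   \code{regions} (named list; names like \code{"2&7"} list the clusters
#'   the region's genes are expressed in)
#' @export
expressedGeneSets <- function(sce, clusters, genes, minFrac = 0.1,
                              whichClusters = NULL) {
  if (length(genes) == 0) stop("empty gene list")
  m <- if (is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "logcounts") else sce
  clusters <- as.factor(clusters)
  if (is.null(whichClusters)) whichClusters <- levels(clusters)
  if (length(whichClusters) < 1) stop("need at least one cluster")
  genes <- intersect(genes, rownames(m))
  sets <- lapply(whichClusters, function(cl) {
    sub <- m[genes, clusters == cl, drop = FALSE]
    genes[Matrix::rowMeans(sub > 0) >= minFrac]
  })
  names(sets) <- whichClusters

  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(genes))
  keys <- apply(membership, 1, function(row)
    paste(whichClusters[row], collapse = "&"))
  detected <- keys != ""
  regions <- split(genes[detected], keys[detected])

  # emit all 2^m - 1 regions, empty ones included
  mC <- length(whichClusters)
  allKeys <- unlist(lapply(seq_len(mC), function(k)
    utils::combn(whichClusters, k, paste, collapse = "&",
                 simplify = TRUE)))
  out <- stats::setNames(vector("list", length(allKeys)), allKeys)
  for (k in allKeys) out[[k]] <- regions[[k]] %||% character(0)
  list(sets = sets, regions = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
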