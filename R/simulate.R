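#' Simulate a droplet scRNA-seq UMI count matrix with known cell types
#'
#' Generates sparse genes x cells UMI counts under a negative-binomial
#' model. Each gene has a baseline relative expression drawn from a
#' log-normal; marker genes of a cell type have their mean multiplied by
#' \code{exp(markerLogFC)} in cells of that type. A contiguous block of 13
#' genes named with the \code{MT-} prefix carries \code{fracMito} of the
#' baseline expression mass, so per-cell mitochondrial fractions scatter
#' around that value. Per-cell library sizes are log-normal. Counts for
#' gene i in cell j of type k are NB with mean
#' \code{L_j * p_ik} and size \code{1/nbDispersion}, where \code{p_ik} is
#' the type-k relative expression profile (columns sum to 1).
#'
#' \code{nAggregate} additional cells are formed by summing the counts of
#' two sampled singlet cells; their detected-gene counts are inflated, which
#' is what the high-complexity QC rule in [qcFilter()] is meant to catch.
#' They carry the ground-truth label \code{"aggregate"}.
#'
#' All randomness flows through one seeded stream per call; the global RNG
#' state is restored on exit, and a fixed seed reproduces the matrix
#' bit-identically.
#'
#' @param params a [ScSimParams] object
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   \code{counts} assay; \code{colData} columns \code{trueType} (the
#'   ground-truth generating type, \code{"aggregate"} for summed cells);
#'   \code{metadata} entries \code{trueMarkers} (list of marker gene sets
#'   per type), \code{typeProfiles} (genes x types relative-expression
#'   matrix) and \code{params}.
#' @examples
#' sce <- simulateSingleCells(ScSimParams(nCells = 200, nGenes = 300,
#'                                        kTypes = 3,
#'                                        typeProps = c(0.5, 0.3, 0.2),
#'                                        markersPerType = 20, seed = 7))
#' table(sce$trueType)
#' @export
simulateSingleCells <- function(params = ScSimParams()) {
  stopifnot(is(params, "ScSimParams"))
  validObject(params)
  p <- params
  nMito <- if (p@fracMito > 0) 13L else 0L
  if (p@nGenes < nMito + p@kTypes * p@markersPerType)
    stop("nGenes too small for the mitochondrial block plus marker blocks")

  geneNames <- sprintf("GENE%04d", seq_len(p@nGenes))
  if (nMito > 0)
    geneNames[seq_len(nMito)] <- sprintf("MT-G%02d", seq_len(nMito))

  withSeed(p@seed, {
    base <- stats::rlnorm(p@nGenes, meanlog = 0, sdlog = 1)
    if (nMito > 0) {
      mito <- seq_len(nMito)
      base[mito] <- base[mito] / sum(base[mito]) * p@fracMito
      base[-mito] <- base[-mito] / sum(base[-mito]) * (1 - p@fracMito)
    } else {
      base <- base / sum(base)
    }

    # disjoint marker blocks placed after the mitochondrial block
    markerIdx <- vector("list", p@kTypes)
    offset <- nMito
    for (k in seq_len(p@kTypes)) {
      markerIdx[[k]] <- offset + seq_len(p@markersPerType)
      offset <- offset + p@markersPerType
    }

    profiles <- matrix(base, nrow = p@nGenes, ncol = p@kTypes,
                       dimnames = list(geneNames,
                                       paste0("type", seq_len(p@kTypes))))
    for (k in seq_len(p@kTypes))
      profiles[markerIdx[[k]], k] <- profiles[markerIdx[[k]], k] *
        exp(p@markerLogFC)
    profiles <- sweep(profiles, 2, colSums(profiles), "/")

    cellType <- sample.int(p@kTypes, p@nCells, replace = TRUE,
                           prob = p@typeProps)
    libSize <- stats::rlnorm(p@nCells, p@libsizeMu, p@libsizeSigma)

    size <- 1 / p@nbDispersion
    # build sparse columns in blocks to bound dense memory
    blocks <- split(seq_len(p@nCells),
                    ceiling(seq_len(p@nCells) / 500))
    cols <- lapply(blocks, function(jj) {
      mu <- profiles[, cellType[jj], drop = FALSE] %*%
        diag(libSize[jj], nrow = length(jj))
      cnt <- matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                   size = size),
                    nrow = p@nGenes)
      methods::as(cnt, "CsparseMatrix")
    })
    counts <- do.call(cbind, cols)

    if (p@nAggregate > 0) {
      pick <- matrix(sample.int(p@nCells, 2L * p@nAggregate, replace = TRUE),
                     ncol = 2)
      agg <- counts[, pick[, 1], drop = FALSE] +
        counts[, pick[, 2], drop = FALSE]
      counts <- cbind(counts, agg)
    }

    barcodes <- sprintf("CELL%05d-1", seq_len(ncol(counts)))
    dimnames(counts) <- list(geneNames, barcodes)
    trueType <- c(paste0("type", cellType),
                  rep("aggregate", p@nAggregate))
    trueMarkers <- lapply(markerIdx, function(i) geneNames[i])
    names(trueMarkers) <- paste0("type", seq_len(p@kTypes))

    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(trueType = trueType,
                                     row.names = barcodes),
      metadata = list(trueMarkers = trueMarkers,
                      typeProfiles = profiles, params = p))
  })
}

#' Simulate bulk tumor expression, receptor status and survival
#'
#' Each tumor draws a generating cell type uniformly; its log2 expression
#' column is \code{purity * profile[type] + (1 - purity) * meanProfile}
#' plus N(0, noiseSD) noise. Receptor status (ER/PR/HER2) comes from the
#' params' \code{subtypeRule}. Overall-survival time is exponential with
#' rate \code{baselineHazard * hazardMultipliers[type]}; an independent
#' exponential censoring time with one global rate (chosen so the marginal
#' censoring probability at the mean hazard is about \code{censorRate})
#' right-censors it.
#'
#' @param params a [BulkSimParams]
#' @param typeProfiles genes x types numeric matrix on the log2 scale
#'   (e.g. per-type mean expression from a single-cell simulation or
#'   experiment); column count must equal the number of types in
#'   \code{params@subtypeRule}
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   \code{log2expr} and \code{colData} columns \code{er}, \code{pr},
#'   \code{her2}, \code{osTime} (months), \code{osEvent} (1 = death) and
#'   the ground truth \code{trueType}.
#' @export
simulateBulk <- function(params, typeProfiles) {
  stopifnot(is(params, "BulkSimParams"))
  validObject(params)
  if (is.null(dim(typeProfiles)) || nrow(typeProfiles) == 0 ||
      ncol(typeProfiles) == 0)
    stop("'typeProfiles' must be a nonempty genes x types matrix")
  k <- nrow(params@subtypeRule)
  if (ncol(typeProfiles) != k)
    stop("'typeProfiles' has ", ncol(typeProfiles),
         " columns but subtypeRule defines ", k, " types")
  if (is.null(colnames(typeProfiles)))
    colnames(typeProfiles) <- params@subtypeRule$type

  withSeed(params@seed, {
    n <- params@nTumors
    gtype <- sample.int(k, n, replace = TRUE)
    meanProf <- rowMeans(typeProfiles)
    expr <- params@purity * typeProfiles[, gtype, drop = FALSE] +
      (1 - params@purity) * meanProf
    if (params@noiseSD > 0)
      expr <- expr + matrix(stats::rnorm(length(expr), 0, params@noiseSD),
                            nrow = nrow(expr))
    samples <- sprintf("TUMOR%04d", seq_len(n))
    dimnames(expr) <- list(rownames(typeProfiles), samples)

    rate <- params@baselineHazard * params@hazardMultipliers[gtype]
    tEvent <- stats::rexp(n, rate = rate)
    if (params@censorRate > 0) {
      cRate <- params@baselineHazard * mean(params@hazardMultipliers) *
        params@censorRate / (1 - params@censorRate)
      tCens <- stats::rexp(n, rate = cRate)
    } else {
      tCens <- rep(Inf, n)
    }
    osTime <- pmin(tEvent, tCens)
    osEvent <- as.integer(tEvent <= tCens)

    rule <- params@subtypeRule[gtype, , drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = expr),
      colData = S4Vectors::DataFrame(
        er = rule$er, pr = rule$pr, her2 = rule$her2,
        osTime = osTime, osEvent = osEvent,
        trueType = colnames(typeProfiles)[gtype],
        row.names = samples),
      metadata = list(params = params))
  })
}

#' Per-type mean expression profiles from a single-cell experiment
#'
#' Averages normalized log expression within each ground-truth (or cluster)
#' label and rescales natural-log values to log2, giving the genes x types
#' profile matrix [simulateBulk()] consumes.
#'
#' @param sce a SingleCellExperiment with a \code{logcounts} assay (see
#'   [normalizeCounts()])
#' @param labels cell labels (defaults to \code{sce$trueType}); cells
#'   labelled \code{"aggregate"} are ignored
#' @return genes x types matrix on the log2 scale
#' @export
typeProfilesFromCells <- function(sce, labels = sce$trueType) {
  m <- SummarizedExperiment::assay(sce, "logcounts")
  keep <- labels != "aggregate"
  m <- m[, keep, drop = FALSE]
  labels <- labels[keep]
  types <- sort(unique(labels))
  prof <- vapply(types, function(t)
    Matrix::rowMeans(m[, labels == t, drop = FALSE]),
    numeric(nrow(m)))
  dimnames(prof) <- list(rownames(m), types)
  prof / log(2)
}
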