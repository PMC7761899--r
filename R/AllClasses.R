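#' @import methods
NULL

#' Parameters for the single-cell UMI count simulator
#'
#' Holds the generative settings for [simulateSingleCells()]: a population of
#' \code{kTypes} discrete cell types mixed in proportions \code{typeProps},
#' each type carrying \code{markersPerType} marker genes whose mean
#' expression is raised by \code{exp(markerLogFC)} relative to other types.
#' Counts are negative-binomial with a shared dispersion; per-cell library
#' sizes are log-normal; a fixed block of 13 \code{MT-}-prefixed genes
#' carries \code{fracMito} of baseline expression mass; \code{nAggregate}
#' extra cells are sums of two sampled cells (high-complexity aggregates
#' that the detected-gene QC filter should remove).
#'
#' The defaults mirror a droplet scRNA-seq study of a dissociated solid
#' tissue: ten cell types with strongly uneven abundances (proportions taken
#' from the published cluster-size distribution of a 3193-cell breast-tissue
#' experiment, 24.1\% down to 1.0\%), a 5\% mitochondrial fraction typical of
#' healthy cells, and median library size around 5000 UMIs.
#'
#' @slot nCells,nGenes,kTypes,markersPerType,nAggregate integer counts
#' @slot typeProps numeric, sums to 1
#' @slot markerLogFC natural-log fold increase of a marker in its own type
#' @slot nbDispersion NB dispersion (variance = mu + dispersion * mu^2)
#' @slot libsizeMu,libsizeSigma log-normal library-size parameters
#' @slot fracMito fraction of baseline expression mass on the MT- block
#' @slot seed integer seed; all randomness flows through it
#' @export
setClass("ScSimParams", slots = c(
  nCells = "integer", nGenes = "integer", kTypes = "integer",
  typeProps = "numeric", markersPerType = "integer", markerLogFC = "numeric",
  nbDispersion = "numeric", libsizeMu = "numeric", libsizeSigma = "numeric",
  fracMito = "numeric", nAggregate = "integer", seed = "integer"
))

setValidity("ScSimParams", function(object) {
  msg <- character()
  for (s in c("nCells", "nGenes", "kTypes", "markersPerType", "nAggregate"))
    if (!isCount(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a nonnegative integer", s))
  if (length(msg)) return(msg)
  if (object@kTypes < 1L) msg <- c(msg, "'kTypes' must be >= 1")
  if (length(object@typeProps) != object@kTypes)
    msg <- c(msg, "'typeProps' length must equal 'kTypes'")
  if (any(object@typeProps < 0) ||
      abs(sum(object@typeProps) - 1) > 1e-9)
    msg <- c(msg, "'typeProps' must be nonnegative and sum to 1 (tol 1e-9)")
  if (object@markersPerType * object@kTypes > object@nGenes)
    msg <- c(msg, "markersPerType * kTypes must not exceed nGenes")
  if (!isProportion(object@fracMito) || object@fracMito >= 1)
    msg <- c(msg, "'fracMito' must be a proportion in [0, 1)")
  if (object@nbDispersion <= 0) msg <- c(msg, "'nbDispersion' must be > 0")
  if (object@libsizeSigma < 0) msg <- c(msg, "'libsizeSigma' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScSimParams-class constructor with study-condition defaults
#' @param nCells,nGenes,kTypes,typeProps,markersPerType,markerLogFC
#'   see slots
#' @param nbDispersion,libsizeMu,libsizeSigma,fracMito,nAggregate,seed
#'   see slots
#' @return a validated \code{ScSimParams} object
#' @export
ScSimParams <- function(nCells = 3193, nGenes = 2000, kTypes = 10,
                        typeProps = c(769, 749, 453, 336, 305, 188, 161,
                                      153, 48, 31) / 3193,
                        markersPerType = 100, markerLogFC = log(4),
                        nbDispersion = 0.5, libsizeMu = log(5000),
                        libsizeSigma = 0.3, fracMito = 0.05,
                        nAggregate = 30, seed = 1L) {
  if (!isCount(nCells) || !isCount(nGenes) || !isCount(kTypes) ||
      !isCount(markersPerType) || !isCount(nAggregate))
    stop("cell, gene, type, marker and aggregate counts must be ",
         "nonnegative integers")
  if (any(typeProps < 0) || any(typeProps > 1))
    stop("'typeProps' entries must be proportions in [0, 1]")
  new("ScSimParams",
      nCells = as.integer(nCells), nGenes = as.integer(nGenes),
      kTypes = as.integer(kTypes), typeProps = as.numeric(typeProps),
      markersPerType = as.integer(markersPerType),
      markerLogFC = as.numeric(markerLogFC),
      nbDispersion = as.numeric(nbDispersion),
      libsizeMu = as.numeric(libsizeMu),
      libsizeSigma = as.numeric(libsizeSigma),
      fracMito = as.numeric(fracMito),
      nAggregate = as.integer(nAggregate), seed = as.integer(seed))
}

setMethod("show", "ScSimParams", function(object) {
  cat("ScSimParams:", object@nCells, "cells x", object@nGenes, "genes,",
      object@kTypes, "types;", object@markersPerType,
      "markers/type at logFC", format(object@markerLogFC, digits = 3),
      "\n  NB dispersion", object@nbDispersion,
      "| mito fraction", object@fracMito,
      "|", object@nAggregate, "aggregate cells | seed", object@seed, "\n")
})

#' Parameters for the bulk-tumor expression and survival simulator
#'
#' Settings for [simulateBulk()]: each tumor's log2 expression profile is a
#' purity-weighted mixture of one generating cell-type profile and the mean
#' profile, plus Gaussian noise; overall-survival times are exponential with
#' a per-type hazard multiplier and independent exponential censoring.
#' \code{subtypeRule} maps each generating type to ER/PR/HER2 receptor
#' status (a data.frame with columns \code{type}, \code{er}, \code{pr},
#' \code{her2}, values \code{"+"}/\code{"-"}).
#'
#' @slot nTumors integer
#' @slot purity weight of the dominant type profile, in (0, 1]
#' @slot noiseSD Gaussian noise sd on the log2 scale
#' @slot subtypeRule data.frame mapping type -> receptor status
#' @slot baselineHazard events per time unit (months)
#' @slot hazardMultipliers per-type positive hazard multipliers
#' @slot censorRate target marginal censoring probability
#' @slot seed integer seed
#' @export
setClass("BulkSimParams", slots = c(
  nTumors = "integer", purity = "numeric", noiseSD = "numeric",
  subtypeRule = "data.frame", baselineHazard = "numeric",
  hazardMultipliers = "numeric", censorRate = "numeric", seed = "integer"
))

setValidity("BulkSimParams", function(object) {
  msg <- character()
  if (!isCount(object@nTumors, min = 1)) msg <- c(msg, "'nTumors' must be a positive integer")
  if (!(object@purity > 0 && object@purity <= 1))
    msg <- c(msg, "'purity' must be in (0, 1]")
  if (object@noiseSD < 0) msg <- c(msg, "'noiseSD' must be >= 0")
  if (!all(c("type", "er", "pr", "her2") %in% names(object@subtypeRule)))
    msg <- c(msg, "'subtypeRule' needs columns type, er, pr, her2")
  if (any(object@hazardMultipliers <= 0))
    msg <- c(msg, "'hazardMultipliers' must be strictly positive")
  if (object@baselineHazard <= 0) msg <- c(msg, "'baselineHazard' must be > 0")
  if (!isProportion(object@censorRate) || object@censorRate >= 1)
    msg <- c(msg, "'censorRate' must be in [0, 1)")
  if (length(msg) == 0 &&
      nrow(object@subtypeRule) != length(object@hazardMultipliers))
    msg <- c(msg, "subtypeRule rows must match hazardMultipliers length")
  if (length(msg)) msg else TRUE
})

#' @describeIn BulkSimParams-class constructor. The default
#'   \code{subtypeRule} covers ten generating types with the four clinical
#'   receptor groups (luminal types ER+HER2-, one ER+HER2+, one ER-HER2+,
#'   basal-like types triple-negative); default survival uses a baseline
#'   hazard of 0.01 events/month with moderate per-type variation and 30
#'   percent censoring, giving median follow-up on the TCGA scale of years.
#' @param nTumors,purity,noiseSD,subtypeRule,baselineHazard see slots
#' @param hazardMultipliers,censorRate,seed see slots
#' @return a validated \code{BulkSimParams} object
#' @export
BulkSimParams <- function(nTumors = 1100, purity = 0.8, noiseSD = 1,
                          subtypeRule = defaultSubtypeRule(10),
                          baselineHazard = 0.01,
                          hazardMultipliers = rep(1, nrow(subtypeRule)),
                          censorRate = 0.3, seed = 1L) {
  if (length(purity) == 1 && !is.na(purity) && purity == 0)
    stop("'purity' must be in (0, 1]; purity = 0 carries no type signal")
  new("BulkSimParams",
      nTumors = as.integer(nTumors), purity = as.numeric(purity),
      noiseSD = as.numeric(noiseSD), subtypeRule = subtypeRule,
      baselineHazard = as.numeric(baselineHazard),
      hazardMultipliers = as.numeric(hazardMultipliers),
      censorRate = as.numeric(censorRate), seed = as.integer(seed))
}

#' Default mapping from generating cell type to receptor status
#'
#' Types are labelled \code{type1..typeK}. The first types are assigned
#' ER+HER2- (luminal-like), then one ER+HER2+, one ER-HER2+, and the
#' remainder triple-negative, echoing the clinical prevalence ordering of
#' breast-tumor subtypes.
#'
#' @param k number of generating types
#' @return data.frame with columns type, er, pr, her2
#' @export
defaultSubtypeRule <- function(k) {
  stopifnot(isCount(k, min = 1))
  er <- pr <- her2 <- rep("-", k)
  nLum <- max(1L, floor(k / 2))
  er[seq_len(nLum)] <- "+"
  pr[seq_len(nLum)] <- "+"
  if (k > nLum) her2[nLum + 1L] <- "+"
  if (k > nLum + 1L) {
    er[nLum + 1L] <- "+"
    her2[nLum + 2L] <- "+"
  }
  data.frame(type = paste0("type", seq_len(k)), er = er, pr = pr,
             her2 = her2, stringsAsFactors = FALSE)
}

setMethod("show", "BulkSimParams", function(object) {
  cat("BulkSimParams:", object@nTumors, "tumors,",
      nrow(object@subtypeRule), "generating types; purity", object@purity,
      "| noise sd", object@noiseSD, "(log2)\n  baseline hazard",
      object@baselineHazard, "/month | censoring", object@censorRate,
      "| seed", object@seed, "\n")
})

#' Named collection of cluster gene signatures
#'
#' An ordered, named list of gene sets, one per cell cluster, optionally
#' backed by the marker-statistics table that produced them. This is the
#' in-memory form of a GMT file: set names are unique, genes within a set
#' are unique and ordered (for cluster signatures, by decreasing average
#' log fold change).
#'
#' @slot sets named list of character vectors
#' @slot descriptions character, one per set (GMT description field)
#' @slot stats data.frame of per-gene marker statistics, or empty
#' @export
setClass("SignatureCollection", slots = c(
  sets = "list", descriptions = "character", stats = "data.frame"
))

setValidity("SignatureCollection", function(object) {
  msg <- character()
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    msg <- c(msg, "set names must be present, nonempty and unique")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "each set must be a character vector of gene symbols")
  if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0))
    msg <- c(msg, "genes within a set must be unique")
  if (length(object@descriptions) != length(object@sets))
    msg <- c(msg, "need one description per set")
  if (length(msg)) msg else TRUE
})

#' @describeIn SignatureCollection-class constructor
#' @param sets named list of character vectors of gene symbols
#' @param descriptions optional character vector, recycled from ""
#' @param stats optional marker-statistics data.frame backing the sets
#' @return a \code{SignatureCollection}
#' @export
SignatureCollection <- function(sets, descriptions = NULL, stats = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (is.null(stats)) stats <- data.frame()
  new("SignatureCollection", sets = sets,
      descriptions = as.character(descriptions), stats = stats)
}

#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' @export
setMethod("names", "SignatureCollection", function(x) names(x@sets))

#' @param x a \code{SignatureCollection}
#' @param i set name or index
#' @rdname SignatureCollection-class
#' @export
setMethod("[[", "SignatureCollection", function(x, i) x@sets[[i]])

#' @rdname SignatureCollection-class
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "SignatureCollection"))
  x@sets
}

setMethod("show", "SignatureCollection", function(object) {
  sizes <- lengths(object@sets)
  cat("SignatureCollection with", length(object@sets), "gene sets\n")
  n <- min(length(sizes), 10L)
  for (i in seq_len(n))
    cat(sprintf("  %s: %d genes\n", names(object@sets)[i], sizes[i]))
  if (length(sizes) > n) cat("  ...\n")
  if (nrow(object@stats))
    cat("  backed by", nrow(object@stats), "marker-statistic rows\n")
})

#' Matrix of per-sample gene-set enrichment scores
#'
#' Gene sets (cell-cluster signatures) in rows, samples (tumors) in columns.
#' Scores are bounded in [-1, +1]. \code{setSizes} records how many
#' signature genes were present in the expression matrix per set, and
#' \code{missingGenes} how many were absent (silently intersected out but
#' counted). \code{geneUniverse} is the number of genes the rank statistic
#' was computed over, on which score magnitudes depend.
#'
#' @slot scores numeric matrix, sets x samples
#' @slot setSizes named integer, genes used per set
#' @slot missingGenes named integer, signature genes absent from the matrix
#' @slot geneUniverse integer, number of genes in the scored matrix
#' @slot mode "max_diff" or "max_dev"
#' @slot tauWeight rank-weight exponent of the walk
#' @export
setClass("GsvaScores", slots = c(
  scores = "matrix", setSizes = "integer", missingGenes = "integer",
  geneUniverse = "integer", mode = "character", tauWeight = "numeric"
))

setValidity("GsvaScores", function(object) {
  msg <- character()
  if (!is.numeric(object@scores)) msg <- c(msg, "scores must be numeric")
  else if (any(is.na(object@scores)) ||
           any(object@scores < -1 - 1e-12) || any(object@scores > 1 + 1e-12))
    msg <- c(msg, "enrichment scores must lie in [-1, +1]")
  if (length(object@setSizes) != nrow(object@scores))
    msg <- c(msg, "need one set size per score row")
  if (!object@mode %in% c("max_diff", "max_dev"))
    msg <- c(msg, "mode must be 'max_diff' or 'max_dev'")
  if (length(msg)) msg else TRUE
})

#' @rdname GsvaScores-class
#' @param object,x a \code{GsvaScores}
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname GsvaScores-class
#' @export
setMethod("scoreMatrix", "GsvaScores", function(x) x@scores)

#' @rdname GsvaScores-class
#' @export
setGeneric("missingGenes", function(x) standardGeneric("missingGenes"))

#' @rdname GsvaScores-class
#' @export
setMethod("missingGenes", "GsvaScores", function(x) x@missingGenes)

#' @rdname GsvaScores-class
#' @export
setMethod("dim", "GsvaScores", function(x) dim(x@scores))

setMethod("show", "GsvaScores", function(object) {
  cat("GsvaScores:", nrow(object@scores), "gene sets x",
      ncol(object@scores), "samples (mode", object@mode,
      ", tau", object@tauWeight, ")\n",
      " gene universe:", object@geneUniverse, "genes\n",
      " score range:",
      paste(format(range(object@scores), digits = 3), collapse = " .. "),
      "\n")
  if (any(object@missingGenes > 0))
    cat("  signature genes missing from matrix:",
        paste0(names(object@missingGenes)[object@missingGenes > 0], "=",
               object@missingGenes[object@missingGenes > 0],
               collapse = ", "), "\n")
})
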