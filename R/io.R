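#' Read a CellRanger-style MatrixMarket triplet directory
#'
#' Expects \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv}
#' (gene id, and optionally symbol) in \code{dir}. Dimensions are checked
#' against the sidecar files and entries must be integral; malformed input
#' is rejected, never coerced.
#'
#' @param dir path to the triplet directory
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer \code{counts} assay, gene symbols as rownames, barcodes as
#'   colnames
#' @export
readMtxTriplet <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing file(s): ", paste(basename(missing), collapse = ", "))
  m <- Matrix::readMM(paths[1])
  if (any(m@x != round(m@x)))
    stop("matrix.mtx: non-integer entries; UMI counts must be integral")
  if (any(m@x < 0))
    stop("matrix.mtx: negative entries")
  barcodes <- readLines(paths[2])
  featLines <- readLines(paths[3])
  feats <- strsplit(featLines, "\t", fixed = TRUE)
  if (length(barcodes) != ncol(m))
    stop(sprintf("barcodes.tsv: %d lines but matrix.mtx declares %d columns",
                 length(barcodes), ncol(m)))
  if (length(featLines) != nrow(m))
    stop(sprintf("features.tsv: %d lines but matrix.mtx declares %d rows",
                 length(featLines), nrow(m)))
  symbols <- vapply(feats, function(f) f[[min(2L, length(f))]], character(1))
  counts <- methods::as(m, "CsparseMatrix")
  dimnames(counts) <- list(symbols, barcodes)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
}

#' Write a UMI count matrix as a MatrixMarket triplet
#'
#' Inverse of [readMtxTriplet()]; round-trips counts bit-identically.
#'
#' @param sce SingleCellExperiment with a \code{counts} assay
#' @param dir output directory, created if needed
#' @return \code{dir}, invisibly
#' @export
writeMtxTriplet <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  writeLines(paste(rownames(counts), rownames(counts), sep = "\t"),
             file.path(dir, "features.tsv"))
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Each tab-separated line is: set name, description, then gene symbols.
#' Lines with fewer than three fields, duplicate set names, duplicate genes
#' within a set, or empty sets are rejected. Gene order is preserved.
#'
#' @param path GMT file path
#' @return a [SignatureCollection]
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  dup <- vapply(sets, anyDuplicated, integer(1))
  if (any(dup > 0))
    stop("duplicate genes within set(s): ",
         paste(nm[dup > 0], collapse = ", "))
  SignatureCollection(sets,
                      descriptions = vapply(fields, `[[`, character(1), 2L))
}

#' Write gene sets to a GMT file
#'
#' @param collection a [SignatureCollection] (or named list of character
#'   vectors)
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGmt <- function(collection, path) {
  if (!is(collection, "SignatureCollection"))
    collection <- SignatureCollection(collection)
  desc <- collection@descriptions
  desc[!nzchar(desc)] <- "na"
  lines <- mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(collection@sets), desc, collection@sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a clinical table (receptor status and overall survival)
#'
#' Tab-separated with a header; required columns \code{sample}, \code{er},
#' \code{pr}, \code{her2} (values \code{+}, \code{-} or \code{NA}),
#' \code{os_time} (nonnegative, months) and \code{os_event} (0/1).
#' Rows with missing fields are flagged in the \code{complete} column, not
#' dropped; the count of usable rows is reported via a message and the
#' \code{"nUsable"} attribute.
#'
#' @param path TSV path
#' @return data.frame with the columns above plus \code{complete}
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          quote = "", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  need <- c("sample", "er", "pr", "her2", "os_time", "os_event")
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("clinical table lacks column(s): ", paste(absent, collapse = ", "))
  for (col in c("er", "pr", "her2")) {
    bad <- !is.na(df[[col]]) & !df[[col]] %in% c("+", "-")
    if (any(bad))
      stop("column '", col, "' has values outside {+, -, NA}: ",
           paste(unique(df[[col]][bad]), collapse = ", "))
  }
  if (any(!is.na(df$os_time) & df$os_time < 0))
    stop("negative os_time in clinical table")
  if (any(!is.na(df$os_event) & !df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1")
  df$complete <- stats::complete.cases(df[, need])
  nUsable <- sum(df$complete)
  message(nrow(df), " rows read; ", nUsable, " with complete clinical fields")
  attr(df, "nUsable") <- nUsable
  df
}

#' Write a genes x samples expression matrix as TSV
#'
#' @param mat numeric matrix with gene rownames and sample colnames
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeExpressionTsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column is the gene identifier; duplicate gene or sample ids and
#' non-finite values are rejected.
#'
#' @param path TSV path
#' @return numeric matrix, genes x samples
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (!is.numeric(m) || any(!is.finite(m)))
    stop("expression values must be finite numbers")
  rownames(m) <- genes
  m
}
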