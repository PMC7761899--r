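#' Assign each tumor its highest-scoring cluster
#'
#' Argmax over the score column of each sample. Exact ties are flagged and
#' broken by the lowest cluster label (first row among the tied maxima).
#' Deterministic: a function of the score matrix only.
#'
#' @param scores a [GsvaScores] or sets x samples numeric matrix
#' @return data.frame with columns \code{sample}, \code{cluster} (the row
#'   name of the winning set), \code{score}, \code{isTie}
#' @export
assignClusters <- function(scores) {
  m <- if (is(scores, "GsvaScores")) scoreMatrix(scores) else as.matrix(scores)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("cluster", seq_len(nrow(m)) - 1L)
  win <- apply(m, 2, which.max)
  top <- m[cbind(win, seq_len(ncol(m)))]
  isTie <- vapply(seq_len(ncol(m)), function(j)
    sum(m[, j] == top[j]) > 1L, logical(1))
  data.frame(sample = colnames(m),
             cluster = rownames(m)[win],
             score = top, isTie = isTie, row.names = NULL)
}

#' Map ER/PR/HER2 receptor status to a clinical subtype
#'
#' ER+HER2- (luminal A-like), ER+HER2+ (luminal B-like), ER-HER2+ (HER2),
#' triple-negative (ER-, PR-, HER2-), and \code{"unknown"} for every other
#' combination including missing stains and the rare ER-PR+HER2- pattern.
#' PR enters only the triple-negative rule. Total function, vectorized.
#'
#' @param er,pr,her2 character vectors with values "+", "-", or NA
#' @return character vector of subtypes
#' @examples
#' mapSubtype(c("+", "-", "-"), c("+", "-", "+"), c("-", "-", "-"))
#' @export
mapSubtype <- function(er, pr, her2) {
  n <- max(length(er), length(pr), length(her2))
  er <- rep_len(as.character(er), n)
  pr <- rep_len(as.character(pr), n)
  her2 <- rep_len(as.character(her2), n)
  out <- rep("unknown", n)
  out[!is.na(er) & !is.na(her2) & er == "+" & her2 == "-"] <- "ER+HER2-"
  out[!is.na(er) & !is.na(her2) & er == "+" & her2 == "+"] <- "ER+HER2+"
  out[!is.na(er) & !is.na(her2) & er == "-" & her2 == "+"] <- "ER-HER2+"
  out[!is.na(er) & !is.na(pr) & !is.na(her2) &
        er == "-" & pr == "-" & her2 == "-"] <- "TNBC"
  out
}

#' Merge cluster assignments with clinical records
#'
#' Joins on sample id and derives the clinical subtype; the result is the
#' per-tumor record table the coverage, cross-tab and survival functions
#' consume.
#'
#' @param assignments data.frame from [assignClusters()]
#' @param clinical data.frame with columns \code{sample}, \code{er},
#'   \code{pr}, \code{her2}, \code{os_time}, \code{os_event} (see
#'   [readClinical()]), or a \code{colData}-style data.frame with
#'   \code{er/pr/her2/osTime/osEvent}
#' @return data.frame of tumor records
#' @export
buildTumorRecords <- function(assignments, clinical) {
  cl <- as.data.frame(clinical)
  if (!"sample" %in% names(cl)) cl$sample <- rownames(cl)
  if ("osTime" %in% names(cl) && !"os_time" %in% names(cl)) {
    cl$os_time <- cl$osTime
    cl$os_event <- cl$osEvent
  }
  merged <- merge(assignments, cl, by = "sample", sort = FALSE)
  merged$subtype <- mapSubtype(merged$er, merged$pr, merged$her2)
  merged
}

#' Per-cluster tumor coverage
#'
#' Counts and percentages (one decimal, half-up) of tumors assigned to each
#' cluster, plus the aggregate share of a named cluster subset — e.g. "the
#' five epithelial/stromal/immune signatures classify 86% of tumors".
#'
#' @param records tumor-record data.frame with a \code{cluster} column
#' @param subset optional character vector of cluster labels to aggregate
#' @return list with \code{table} (cluster, n, percent; percent computed on
#'   the full record count), \code{total}, and if \code{subset} given:
#'   \code{subsetCount}, \code{subsetPercent} (sum of the members' rounded
#'   percentages) and \code{subsetPercentRaw} (subset count / total)
#' @export
coverageReport <- function(records, subset = NULL) {
  if (nrow(records) == 0) stop("empty record set")
  tab <- table(records$cluster)
  total <- sum(tab)
  out <- list(table = data.frame(
    cluster = names(tab), n = as.integer(tab),
    percent = roundHalfUp(100 * as.integer(tab) / total, 1),
    row.names = NULL), total = total)
  if (!is.null(subset)) {
    member <- out$table$cluster %in% subset
    out$subsetCount <- sum(out$table$n[member])
    out$subsetPercent <- roundHalfUp(sum(out$table$percent[member]), 1)
    out$subsetPercentRaw <- roundHalfUp(100 * out$subsetCount / total, 1)
  }
  out
}

#' Cluster distribution within each clinical subtype
#'
#' Within-subtype percentages of assigned clusters; each row sums to 100.
#' Tumors of subtype \code{"unknown"} are excluded; subtypes with zero
#' tumors are omitted with a warning.
#'
#' @param records tumor-record data.frame with \code{cluster} and
#'   \code{subtype} columns
#' @return matrix subtypes x clusters of within-subtype percentages (one
#'   decimal, half-up)
#' @export
subtypeCrosstab <- function(records) {
  rec <- records[records$subtype != "unknown", , drop = FALSE]
  subtypes <- c("ER+HER2-", "ER+HER2+", "ER-HER2+", "TNBC")
  absent <- setdiff(subtypes, unique(rec$subtype))
  if (length(absent))
    warning("subtype(s) with zero tumors omitted: ",
            paste(absent, collapse = ", "))
  subtypes <- intersect(subtypes, unique(rec$subtype))
  clusters <- sort(unique(records$cluster))
  out <- t(vapply(subtypes, function(s) {
    tab <- table(factor(rec$cluster[rec$subtype == s], levels = clusters))
    100 * as.numeric(tab) / sum(tab)
  }, numeric(length(clusters))))
  dimnames(out) <- list(subtypes, clusters)
  roundHalfUp(out, 1)
}

#' Mean signature scores within each designated tumor group
#'
#' For tumors designated to each cluster, the mean score of every cluster
#' signature, with a rank-sum p-value comparing the designated cluster's
#' scores against each other cluster's scores within the group (the
#' box-plot summary showing that the winning signature's scores are
#' genuinely higher, not narrowly ahead).
#'
#' @param scores a [GsvaScores] (or sets x samples matrix)
#' @param assignments data.frame from [assignClusters()]
#' @return list with \code{means} (designated group x signature matrix)
#'   and \code{pValues} (same shape; p of designated-vs-that-signature
#'   rank-sum within the group, NA on the diagonal)
#' @export
groupScoreSummary <- function(scores, assignments) {
  m <- if (is(scores, "GsvaScores")) scoreMatrix(scores) else as.matrix(scores)
  groups <- sort(unique(assignments$cluster))
  means <- pv <- matrix(NA_real_, length(groups), nrow(m),
                        dimnames = list(groups, rownames(m)))
  for (g in groups) {
    cols <- assignments$sample[assignments$cluster == g]
    sub <- m[, colnames(m) %in% cols, drop = FALSE]
    means[g, ] <- rowMeans(sub)
    for (k in rownames(m)) {
      if (k == g) next
      both <- c(sub[g, ], sub[k, ])
      pv[g, k] <- wilcoxonP(both,
                            rep(c(TRUE, FALSE), each = ncol(sub)))
    }
  }
  list(means = means, pValues = pv)
}
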