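#' Kaplan-Meier product-limit survival curve
#'
#' At each distinct event time t: n(t) subjects at risk (subjects censored
#' exactly at t still count as at risk — the standard convention), d(t)
#' events, and \code{S(t) = prod_{u <= t} (1 - d(u)/n(u))}. With no
#' censoring this equals the empirical survival function.
#'
#' @param times nonnegative follow-up times
#' @param events event indicators (1 = event, 0 = censored)
#' @return data.frame of class \code{"kmCurve"} with one row per distinct
#'   event time: \code{time}, \code{nRisk}, \code{nEvent}, \code{surv};
#'   attribute \code{"censorTimes"} lists censoring times
#' @export
kmCurve <- function(times, events) {
  if (length(times) == 0) stop("empty input")
  if (any(times < 0)) stop("negative times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  et <- sort(unique(times[events == 1]))
  nRisk <- vapply(et, function(t) sum(times >= t), numeric(1))
  nEvent <- vapply(et, function(t) sum(times == t & events == 1),
                   numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  out <- data.frame(time = et, nRisk = nRisk, nEvent = nEvent, surv = surv)
  attr(out, "censorTimes") <- sort(times[events == 0])
  class(out) <- c("kmCurve", "data.frame")
  out
}

# Pooled event-time table across G groups: per distinct event time,
# at-risk and event counts per group, plus expected events and the
# hypergeometric variance-covariance increments.
logrankTable <- function(times, events, group) {
  group <- as.factor(group)
  G <- nlevels(group)
  et <- sort(unique(times[events == 1]))
  O <- E <- numeric(G)
  V <- matrix(0, G, G)
  for (t in et) {
    atRisk <- times >= t
    n <- sum(atRisk)
    if (n < 1) next
    ng <- vapply(levels(group), function(g) sum(atRisk & group == g),
                 numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(times == t & events == 1 & group == g), numeric(1))
    d <- sum(dg)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      frac <- ng / n
      V <- V + d * (n - d) / (n - 1) *
        (diag(frac, G) - outer(frac, frac))
    }
  }
  list(levels = levels(group), observed = O, expected = E, V = V)
}

#' Log-rank test across survival groups (with optional trend variant)
#'
#' Compares observed and expected event counts over the pooled event-time
#' table. The G-group statistic is the quadratic form
#' \code{(O - E)' V^- (O - E)} on the hypergeometric variance-covariance
#' matrix (generalized inverse; df = G - 1). With \code{trendScores}, the
#' 1-df trend statistic \code{(sum s_g (O_g - E_g))^2 / (s' V s)} tests an
#' ordered alternative; with scores (0, 1) on two groups it equals the
#' two-group statistic.
#'
#' @param times,events pooled follow-up times and 0/1 event indicators
#' @param group group label per subject (>= 2 nonempty groups)
#' @param trendScores optional numeric scores, one per group (sorted group
#'   level order); default NULL = no trend test
#' @return list of class \code{"logrankTest"}: \code{observed},
#'   \code{expected} (named per group), \code{statistic}, \code{df},
#'   \code{pValue}, and when requested \code{trendStatistic},
#'   \code{trendP}
#' @export
logrankTest <- function(times, events, group, trendScores = NULL) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need at least 2 nonempty groups")
  group <- droplevels(group)
  tab <- logrankTable(times, events, group)
  out <- list(observed = stats::setNames(tab$observed, tab$levels),
              expected = stats::setNames(tab$expected, tab$levels))
  if (sum(tab$observed) == 0) {
    warning("zero events in all groups; log-rank p set to 1")
    out$statistic <- 0
    out$df <- nlevels(group) - 1L
    out$pValue <- 1
  } else {
    oe <- tab$observed - tab$expected
    G <- length(oe)
    Vsub <- tab$V[-G, -G, drop = FALSE]
    stat <- drop(t(oe[-G]) %*% pseudoInverse(Vsub) %*% oe[-G])
    out$statistic <- stat
    out$df <- G - 1L
    out$pValue <- stats::pchisq(stat, df = G - 1, lower.tail = FALSE)
  }
  if (!is.null(trendScores)) {
    if (length(trendScores) != nlevels(group))
      stop("need one trend score per group")
    s <- as.numeric(trendScores)
    U <- sum(s * (tab$observed - tab$expected))
    VU <- drop(t(s) %*% tab$V %*% s)
    if (VU <= 0) {
      warning("degenerate trend variance; trend p set to 1")
      out$trendStatistic <- 0
      out$trendP <- 1
    } else {
      out$trendStatistic <- U^2 / VU
      out$trendP <- stats::pchisq(U^2 / VU, df = 1, lower.tail = FALSE)
    }
  }
  class(out) <- "logrankTest"
  out
}

#' @export
print.logrankTest <- function(x, ...) {
  cat("Log-rank test:", length(x$observed), "groups\n")
  print(data.frame(observed = x$observed, expected = x$expected))
  cat(sprintf("chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$pValue))
  if (!is.null(x$trendP))
    cat(sprintf("trend chi-square = %.4g on 1 df, p = %.4g\n",
                x$trendStatistic, x$trendP))
  invisible(x)
}

#' Mantel-Haenszel hazard ratio between two survival groups
#'
#' From the two-group log-rank observed/expected events:
#' \code{HR = (O_a / E_a) / (O_b / E_b)}, with the 95 percent confidence
#' interval \code{exp(ln HR +/- 1.96 sqrt(1/E_a + 1/E_b))}. Satisfies
#' \code{hazardRatio(a, b) = 1 / hazardRatio(b, a)}.
#'
#' @param timesA,eventsA follow-up and 0/1 events of group A
#' @param timesB,eventsB follow-up and 0/1 events of group B
#' @param conf confidence level (default 0.95)
#' @return list of class \code{"hazardRatio"}: \code{hr}, \code{ciLow},
#'   \code{ciHigh}, \code{observed}, \code{expected}
#' @export
hazardRatio <- function(timesA, eventsA, timesB, eventsB, conf = 0.95) {
  if (sum(eventsA) < 1 || sum(eventsB) < 1)
    stop("both groups need at least one event")
  times <- c(timesA, timesB)
  events <- c(eventsA, eventsB)
  group <- rep(c("A", "B"), c(length(timesA), length(timesB)))
  tab <- logrankTable(times, events, group)
  O <- tab$observed
  E <- tab$expected
  if (any(E == 0)) stop("zero expected events in one group")
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / E[1] + 1 / E[2])
  out <- list(hr = unname(hr),
              ciLow = unname(exp(log(hr) - zq * se)),
              ciHigh = unname(exp(log(hr) + zq * se)),
              observed = stats::setNames(O, c("A", "B")),
              expected = stats::setNames(E, c("A", "B")))
  class(out) <- "hazardRatio"
  out
}

#' @export
print.hazardRatio <- function(x, ...) {
  cat(sprintf("Mantel-Haenszel HR = %.4f (95%% CI %.3f-%.3f)\n",
              x$hr, x$ciLow, x$ciHigh))
  invisible(x)
}

#' Survival comparison across assigned clusters
#'
#' Filters tumor records to a clinical subtype and/or a set of clusters,
#' then computes one Kaplan-Meier curve per cluster, the overall log-rank
#' test, the 1-df log-rank trend test (scores = equally spaced cluster
#' ranks in label order), and pairwise Mantel-Haenszel hazard ratios
#' against a reference cluster.
#'
#' @param records tumor-record data.frame with \code{cluster},
#'   \code{subtype}, \code{os_time}, \code{os_event}
#' @param subtypeFilter optional subtype to keep (e.g. "TNBC")
#' @param clusters optional cluster labels to keep
#' @param reference reference cluster for hazard ratios (default: lowest
#'   label present)
#' @return list of class \code{"clusterSurvival"}: \code{curves} (named
#'   list of [kmCurve()] tables), \code{logrank}, \code{hazardRatios}
#'   (named list vs reference), \code{n} per cluster
#' @export
survivalByCluster <- function(records, subtypeFilter = NULL,
                              clusters = NULL, reference = NULL) {
  rec <- records
  if (!is.null(subtypeFilter))
    rec <- rec[rec$subtype %in% subtypeFilter, , drop = FALSE]
  if (!is.null(clusters))
    rec <- rec[rec$cluster %in% clusters, , drop = FALSE]
  rec <- rec[!is.na(rec$os_time) & !is.na(rec$os_event), , drop = FALSE]
  present <- sort(unique(rec$cluster))
  counts <- table(rec$cluster)
  empty <- setdiff(clusters %||% present, present)
  if (length(empty))
    warning("cluster(s) with zero tumors dropped: ",
            paste(empty, collapse = ", "))
  if (length(present) < 2)
    stop("fewer than 2 clusters with tumors after filtering")

  curves <- lapply(present, function(cl) {
    i <- rec$cluster == cl
    kmCurve(rec$os_time[i], rec$os_event[i])
  })
  names(curves) <- present

  lr <- logrankTest(rec$os_time, rec$os_event, rec$cluster,
                    trendScores = seq_along(present))

  if (is.null(reference)) reference <- present[1]
  others <- setdiff(present, reference)
  refIdx <- rec$cluster == reference
  hrs <- lapply(others, function(cl) {
    i <- rec$cluster == cl
    tryCatch(hazardRatio(rec$os_time[i], rec$os_event[i],
                         rec$os_time[refIdx], rec$os_event[refIdx]),
             error = function(e) NULL)
  })
  names(hrs) <- others

  structure(list(curves = curves, logrank = lr, hazardRatios = hrs,
                 n = counts, reference = reference),
            class = "clusterSurvival")
}

#' @export
print.clusterSurvival <- function(x, ...) {
  cat("Survival by cluster (n):\n")
  print(x$n)
  print(x$logrank)
  cat("Hazard ratios vs cluster", x$reference, ":\n")
  for (nm in names(x$hazardRatios))
    if (!is.null(x$hazardRatios[[nm]])) {
      cat(" ", nm, ": ")
      print(x$hazardRatios[[nm]])
    }
  invisible(x)
}
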