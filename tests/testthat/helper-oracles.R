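# Independent brute-force oracles. These deliberately re-derive each
# quantity with naive loops/enumeration, never by calling the package's
# own code paths.

# Gaussian kernel CDF by explicit double loop, bandwidth = sd/4.
oracleKcdf <- function(x) {
  p <- nrow(x); n <- ncol(x)
  z <- matrix(NA_real_, p, n)
  for (i in seq_len(p)) {
    s <- sd(x[i, ])
    if (s == 0) { z[i, ] <- 0.5; next }
    h <- s / 4
    for (j in seq_len(n)) {
      acc <- 0
      for (w in seq_len(n)) acc <- acc + pnorm((x[i, j] - x[i, w]) / h)
      z[i, j] <- acc / n
    }
  }
  z
}

# Enrichment score by explicit O(p^2) walk: for every prefix length,
# recompute the in-set weight sum and out-of-set count from scratch.
oracleES <- function(z, setIdx, j, tauWeight = 1, mode = "max_diff") {
  p <- nrow(z)
  ord <- order(-z[, j], seq_len(p))
  tau <- integer(p); tau[ord] <- seq_len(p)
  r <- abs(p / 2 - tau)
  m <- length(setIdx)
  denomIn <- sum(r[setIdx]^tauWeight)
  degenerate <- denomIn == 0  # all set genes at the fold point (r = 0)
  nu <- numeric(p)
  for (l in seq_len(p)) {
    pre <- ord[seq_len(l)]
    inPre <- pre[pre %in% setIdx]
    inTerm <- if (degenerate) length(inPre) / m
              else sum(r[inPre]^tauWeight) / denomIn
    nu[l] <- inTerm - sum(!(pre %in% setIdx)) / (p - m)
  }
  if (mode == "max_diff") max(nu) + min(nu) else nu[which.max(abs(nu))]
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every split of the
# pooled sample into the two groups (mid-ranks; ties handled by
# conditioning on the observed values).
oracleWilcoxonP <- function(xIn, xOut) {
  pooled <- c(xIn, xOut)
  n1 <- length(xIn)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  splits <- combn(length(pooled), n1)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  pLow <- mean(stats <= obs)
  pHigh <- mean(stats >= obs)
  min(1, 2 * min(pLow, pHigh))
}

# Kaplan-Meier by direct product over observed event times.
oracleKM <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(et))
  for (k in seq_along(et)) {
    t <- et[k]
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
    out[k] <- s
  }
  data.frame(time = et, surv = out)
}

# small deterministic normalized-count fixture: genes x cells matrix with
# block-separated groups, as a plain dense matrix
makeBlockMatrix <- function(nGenesPerBlock = 5, nCellsPerBlock = 4,
                            nBlocks = 2, hi = 5, lo = 0.2, seed = 99) {
  set.seed(seed)
  p <- nGenesPerBlock * nBlocks
  n <- nCellsPerBlock * nBlocks
  m <- matrix(rpois(p * n, lo), p, n)
  for (b in seq_len(nBlocks)) {
    gi <- (b - 1) * nGenesPerBlock + seq_len(nGenesPerBlock)
    ci <- (b - 1) * nCellsPerBlock + seq_len(nCellsPerBlock)
    m[gi, ci] <- rpois(nGenesPerBlock * nCellsPerBlock, hi)
  }
  dimnames(m) <- list(paste0("G", seq_len(p)), paste0("C", seq_len(n)))
  m
}
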