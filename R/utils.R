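#' Round half away from zero
#'
#' Fixed-digit rounding where a trailing 5 always rounds up (for positive
#' input), matching how percentages and fold ratios are conventionally
#' printed in clinical tables. Base \code{round()} rounds half to even,
#' which would print 86.05 as 86.0 rather than 86.1.
#'
#' @param x numeric vector (nonnegative in all package uses)
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate expr with a private RNG stream: seed locally, restore the global
# .Random.seed afterwards so simulation calls leave no global state behind.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# scalar type checks used by validity methods and argument guards
isCount <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < .Machine$double.eps^0.5
}

isProportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Moore-Penrose pseudo-inverse via SVD; used for the log-rank
# variance-covariance quadratic form when the covariance is singular.
pseudoInverse <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
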