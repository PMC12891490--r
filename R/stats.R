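# Shared nonparametric statistics: two-sided Wilcoxon rank-sum, paired
# two-tailed sign test, and FDR correction. Scalar tests wrap the base R
# implementations; a vectorized tie-corrected normal-approximation rank-sum
# serves the large per-time-point families (cross-checked against
# wilcox.test in the test suite).

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration for small samples (both n <= 10, no ties), otherwise
#' the normal approximation with tie correction (via [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @return list(statistic, p, nX, nY, direction).
#' @export
rankSumTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  if (diff(range(c(x, y))) == 0)
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                nX = length(x), nY = length(y), direction = "none"))
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       nX = length(x), nY = length(y),
       direction = if (median(x) > median(y)) "greater"
                   else if (median(x) < median(y)) "less" else "none")
}

#' Paired two-tailed sign test
#'
#' Exact two-sided binomial test on the count of positive differences; tied
#' (zero) differences are dropped. With all pairs tied the result is
#' undefined (NA).
#'
#' @param x differences, or the first sample if `y` is given.
#' @param y optional second paired sample.
#' @return list(nPos, nNeg, p); p is NA when all pairs are tied.
#' @export
signTest <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d) & d != 0]
  if (!length(d)) return(list(nPos = 0L, nNeg = 0L, p = NA_real_))
  nPos <- sum(d > 0)
  bt <- stats::binom.test(nPos, length(d), p = 0.5,
                          alternative = "two.sided")
  list(nPos = nPos, nNeg = length(d) - nPos, p = bt$p.value)
}

#' False-discovery-rate correction
#'
#' Step-up adjusted p-values (Benjamini-Hochberg by default,
#' Benjamini-Yekutieli optionally) and the rejection mask at level q.
#'
#' @param pvals vector of raw p-values (NAs pass through).
#' @param q FDR level (default 0.05).
#' @param method "bh" or "by".
#' @return list(pAdj, mask).
#' @export
fdrCorrect <- function(pvals, q = 0.05, method = c("bh", "by")) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  pAdj <- stats::p.adjust(pvals, method = toupper(method))
  list(pAdj = pAdj, mask = !is.na(pAdj) & pAdj <= q)
}

# Vectorized two-sided rank-sum p-values: each row of X (time x samples)
# against the fixed sample y; normal approximation with tie correction and
# continuity correction, matching wilcox.test(correct = TRUE) for moderate n.
ranksumVec <- function(X, y) {
  X <- as.matrix(X)
  nT <- nrow(X)
  p <- rep(NA_real_, nT)
  ny <- length(y)
  for (i in seq_len(nT)) {
    x <- X[i, ]
    x <- x[!is.na(x)]
    nx <- length(x)
    if (!nx || !ny) next
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) { p[i] <- 1; next }
    z <- W - nx * ny / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[i] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  p
}
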