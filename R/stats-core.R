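#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Compares two samples by rank, using mid-ranks for ties. For small
#' tie-free instances (total size at most `exactMax`) the exact null
#' distribution of the rank-sum statistic is used; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' `tail = "lower"` tests the alternative that `x` tends to take lower
#' values than `y`; `"upper"` the reverse.
#'
#' @param x,y non-empty numeric vectors.
#' @param tail one of `"two.sided"`, `"lower"`, `"upper"`.
#' @param exactMax largest combined sample size for which the exact
#'   distribution is enumerated (default 12); ties always force the
#'   approximation.
#' @return list with `statistic` (the Mann-Whitney U of `x`), `p.value`,
#'   `method`, `tail`.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4), tail = "lower")$p.value  # exactly 1/6
#' @export
rankSumTest <- function(x, y, tail = c("two.sided", "lower", "upper"),
                        exactMax = 12L) {
  tail <- match.arg(tail)
  if (length(x) == 0L || length(y) == 0L)
    fail("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) fail("non-finite values in input")
  alt <- switch(tail, two.sided = "two.sided", lower = "less",
                upper = "greater")
  hasTies <- anyDuplicated(c(x, y)) > 0L
  exact <- !hasTies && (length(x) + length(y)) <= exactMax
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "rank-sum (exact)" else
         "rank-sum (normal approximation, tie + continuity corrected)",
       tail = tail)
}

#' Spearman rank correlation
#'
#' Mid-rank Pearson correlation on ranks. For small tie-free samples
#' (n at most `exactMax`) the p-value comes from the exact/AS89 null
#' distribution of the rank statistic; otherwise from the two-sided t
#' approximation. A constant input vector leaves the coefficient
#' undefined: `rho` is `NA` and `defined` is `FALSE`.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @param exactMax largest n for which the exact null distribution is
#'   used (default 12); ties always force the approximation.
#' @return list with `rho`, `p.value`, `n`, `defined`.
#' @export
spearmanCor <- function(x, y, exactMax = 12L) {
  if (length(x) != length(y)) fail("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) fail("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p.value = NA_real_, n = length(x),
                defined = FALSE))
  }
  exact <- length(x) <= exactMax &&
    anyDuplicated(x) == 0L && anyDuplicated(y) == 0L
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ht$estimate), p.value = min(ht$p.value, 1),
       n = length(x), defined = TRUE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the output keeps the
#' input order. Input values outside \[0, 1\] are an error rather than
#' silently clamped.
#'
#' @param p numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return adjusted values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) fail("'p' must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) fail("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Set-overlap significance
#'
#' Tests whether the overlap `k` between a set of size `a` and a set of
#' size `b`, drawn from a universe of size `n`, exceeds chance.
#' `method = "fisher"` gives the hypergeometric upper-tail probability
#' P(overlap >= k); `method = "chisq"` the 2x2 chi-square test with one
#' degree of freedom (no continuity correction, so a table exactly at its
#' expectation scores statistic 0, p = 1).
#'
#' @param k observed overlap; `a`, `b` the set sizes; `n` the universe.
#' @param method `"fisher"` or `"chisq"`.
#' @return list with `statistic`, `p.value`, `method`, `tail`.
#' @export
overlapTest <- function(k, a, b, n, method = c("fisher", "chisq")) {
  method <- match.arg(method)
  for (v in c("k", "a", "b", "n")) assertScalarNumber(get(v), v, lower = 0)
  if (a > n || b > n) fail("set sizes cannot exceed the universe")
  if (k > min(a, b) || k < max(0, a + b - n))
    fail("overlap inconsistent with the set and universe sizes")
  if (method == "fisher") {
    p <- stats::phyper(k - 1, a, n - a, b, lower.tail = FALSE)
    list(statistic = as.numeric(k), p.value = p,
         method = "hypergeometric (Fisher) overlap", tail = "upper")
  } else {
    tab <- matrix(c(k, a - k, b - k, n - a - b + k), nrow = 2L)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "chi-square 2x2 overlap", tail = "two.sided")
  }
}

#' Principal component analysis with a fixed sign convention
#'
#' SVD-based PCA of a samples x features matrix. Features are centered,
#' not scaled. Component signs are fixed so that the largest-magnitude
#' loading of each component is positive, making results reproducible
#' across platforms.
#'
#' @param x numeric matrix, samples in rows.
#' @param nComponents number of components to return; silently truncated
#'   to the matrix rank with a warning.
#' @return list with `scores` (samples x components), `loadings`
#'   (features x components) and `varianceFraction`.
#' @export
pcaScores <- function(x, nComponents = min(dim(x))) {
  if (any(!is.finite(x))) fail("non-finite values in input")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (nComponents > rank) {
    warning(sprintf("nComponents reduced from %d to the rank %d",
                    nComponents, rank))
    nComponents <- rank
  }
  idx <- seq_len(nComponents)
  load <- pc$rotation[, idx, drop = FALSE]
  sco <- pc$x[, idx, drop = FALSE]
  for (j in idx) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) {
      load[, j] <- -load[, j]
      sco[, j] <- -sco[, j]
    }
  }
  totVar <- sum(pc$sdev^2)
  list(scores = sco, loadings = load,
       varianceFraction = pc$sdev[idx]^2 / totVar)
}

#' Ward hierarchical clustering on Euclidean distances
#'
#' Ward.D2 linkage (squared-Euclidean merge updates) on the Euclidean
#' distance matrix of the rows, with flat cluster labels at `k`.
#'
#' @param x numeric matrix, observations in rows.
#' @param k number of flat clusters to cut (default 2).
#' @return list with `hclust` (the full dendrogram) and `labels`
#'   (integer cluster assignment per row).
#' @export
wardCluster <- function(x, k = 2L) {
  if (nrow(x) < 2L) fail("need at least 2 rows to cluster")
  if (any(!is.finite(x))) fail("non-finite values in input")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  list(hclust = hc, labels = stats::cutree(hc, k = k))
}
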