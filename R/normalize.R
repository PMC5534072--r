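#' Median-of-ratios size factors
#'
#' For sample j, the size factor is the median over genes (restricted to
#' genes with a finite log geometric mean, i.e. nonzero in every sample)
#' of `count[g, j] / geometricMean(count[g, ])`. Factors are returned as
#' computed, without rescaling to geometric mean one.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
  if (any(counts < 0)) fail("negative counts")
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    fail("no gene has nonzero counts in every sample; ",
         "size factors are undefined — filter samples or genes first")
  sf <- apply(counts, 2L, function(cnts)
    exp(stats::median(log(cnts[use]) - logGeo[use])))
  names(sf) <- colnames(counts)
  sf
}

#' Log-like variance-stabilizing transform
#'
#' `log2(count / sizeFactor + pseudocount)`, the monotone "log-like"
#' normalization applied ahead of indices, PCA and clustering.
#'
#' @param counts genes x samples count matrix.
#' @param sizeFactors per-sample positive factors; computed with
#'   [computeSizeFactors()] when missing.
#' @param pseudocount positive offset (default 1).
#' @return a [NormalizedExpression] with transform `"log_like"`.
#' @export
logLikeTransform <- function(counts, sizeFactors = NULL, pseudocount = 1) {
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  if (length(sizeFactors) != ncol(counts))
    fail("one size factor per sample required")
  if (any(sizeFactors <= 0)) fail("size factors must be positive")
  assertScalarNumber(pseudocount, "pseudocount")
  if (pseudocount <= 0) fail("pseudocount must be positive")
  v <- log2(sweep(counts, 2L, sizeFactors, "/") + pseudocount)
  NormalizedExpression(v, sizeFactors, transforms = "log_like")
}

#' Remove linear covariate signal from normalized expression
#'
#' Per gene, fits ordinary least squares of expression on the covariate
#' (with intercept) and replaces values by residuals re-centered at the
#' gene mean, so the result stays on the expression scale while its
#' per-gene correlation with the covariate is exactly zero. Used to
#' regress the alignment-quality covariate (PRUA) out of normalized
#' expression.
#'
#' @param norm a [NormalizedExpression].
#' @param covariate numeric vector, one value per sample, non-constant.
#' @return a [NormalizedExpression] with `"residualized"` appended to its
#'   provenance.
#' @export
residualize <- function(norm, covariate) {
  stopifnot(is(norm, "NormalizedExpression"))
  v <- exprValues(norm)
  if (length(covariate) != ncol(v))
    fail("covariate length must equal the number of samples")
  if (stats::sd(covariate) == 0) fail("constant covariate")
  cen <- covariate - mean(covariate)
  beta <- as.vector(v %*% cen) / sum(cen^2)
  out <- v - outer(beta, cen)
  NormalizedExpression(out, sampleSizeFactors(norm),
                       transforms = c(transforms(norm), "residualized"))
}

#' Row-wise z-scoring with population SD
#'
#' Centers each row at 0 and scales to population (denominator n)
#' standard deviation 1. Rows with zero spread are set to 0 and reported
#' in the `"zeroSdRows"` attribute rather than producing NaN.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape; attribute `zeroSdRows` lists the
#'   flagged row names (or indices when unnamed).
#' @export
zscoreRows <- function(x) {
  m <- rowMeans(x)
  s <- rowSdPop(x)
  zero <- s == 0
  s[zero] <- 1
  z <- (x - m) / s
  z[zero, ] <- 0
  attr(z, "zeroSdRows") <-
    if (is.null(rownames(x))) which(zero) else rownames(x)[zero]
  z
}

#' Standard normalization pipeline
#'
#' Counts -> median-of-ratios size factors -> log-like transform ->
#' (optionally) residualization on a covariate, in that order; the
#' provenance of the result records exactly the transforms applied.
#'
#' @param counts genes x samples count matrix.
#' @param covariate optional per-sample covariate (e.g. PRUA) to
#'   residualize out.
#' @param pseudocount see [logLikeTransform()].
#' @return a [NormalizedExpression].
#' @export
normalizePipeline <- function(counts, covariate = NULL, pseudocount = 1) {
  norm <- logLikeTransform(counts, pseudocount = pseudocount)
  if (!is.null(covariate)) norm <- residualize(norm, covariate)
  norm
}
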