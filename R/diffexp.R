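# Covariate-adjusted negative-binomial likelihood-ratio differential
# expression. This is a transparent stand-in for a full shrinkage-based
# NB pipeline: per-gene method-of-moments dispersion with trend
# shrinkage, maximum-likelihood GLM fits at fixed dispersion, and a
# chi-square(1) likelihood-ratio test of the disorder term. No Cox-Reid
# adjustment, outlier filtering or fold-change shrinkage is applied.

#' Method-of-moments dispersion estimates with trend shrinkage
#'
#' On size-factor-normalized counts, estimates per-gene dispersion as
#' `max(0, (s2 - mu) / mu^2)` where `mu` is the overall normalized mean
#' and `s2` the within-group pooled variance (so planted group effects do
#' not inflate dispersion). Raw estimates are then shrunk toward a
#' fitted mean-dispersion trend `a0 + a1 / mu` by weight `shrink`.
#'
#' @param counts genes x samples count matrix.
#' @param group factor separating the sample groups (residual variance is
#'   pooled within its levels).
#' @param sizeFactors per-sample factors; computed when missing.
#' @param shrink weight of the trend in the shrunk estimate (0 = raw
#'   method of moments, 1 = pure trend); default 0.7.
#' @return named per-gene dispersion vector; all-zero genes are `NA`.
#' @export
estimateDispersionsMoM <- function(counts, group, sizeFactors = NULL,
                                   shrink = 0.7) {
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  group <- as.factor(group)
  q <- sweep(counts, 2L, sizeFactors, "/")
  muBar <- rowMeans(q)
  lv <- levels(group)
  ssq <- matrix(0, nrow(q), 1L)
  df <- 0
  pooled <- rep(0, nrow(q))
  for (g in lv) {
    qg <- q[, group == g, drop = FALSE]
    ng <- ncol(qg)
    if (ng < 2L) next
    pooled <- pooled + rowSums((qg - rowMeans(qg))^2)
    df <- df + (ng - 1L)
  }
  if (df < 1L) fail("need at least two samples in some group")
  s2 <- pooled / df
  raw <- pmax(0, (s2 - muBar) / muBar^2)
  raw[muBar == 0] <- NA_real_
  # parametric mean-dispersion trend alpha(mu) = a0 + a1/mu
  use <- !is.na(raw) & raw > 0 & muBar > 1
  if (sum(use) >= 10L) {
    fit <- stats::lm(raw[use] ~ I(1 / muBar[use]))
    a0 <- max(stats::coef(fit)[1L], 1e-4)
    a1 <- max(stats::coef(fit)[2L], 0)
  } else {
    a0 <- max(stats::median(raw[!is.na(raw)]), 1e-4); a1 <- 0
  }
  trend <- a0 + a1 / muBar
  out <- (1 - shrink) * raw + shrink * trend
  out[is.na(raw)] <- NA_real_
  stats::setNames(out, rownames(counts))
}

# rank check with an informative error naming the collinear columns
checkFullRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    fail("design matrix is singular; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  invisible(TRUE)
}

nbLogLik <- function(y, mu, alpha) {
  if (alpha < 1e-8) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

fitNbGlm <- function(X, y, offset, alpha) {
  fam <- if (alpha < 1e-8) stats::poisson(link = "log")
    else MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)))
  list(logLik = nbLogLik(y, fit$fitted.values, alpha),
       coef = fit$coefficients, converged = fit$converged)
}

#' Negative-binomial likelihood-ratio differential expression
#'
#' For one case/control contrast, fits per gene a log-link NB GLM with
#' log size factors as offsets under the full design
#' (covariates + disorder) and the nested reduced design (covariates
#' only), at the gene's fixed dispersion, and tests the disorder term by
#' `2 * (llFull - llReduced) ~ chi-square(1)`. The log2 fold change is
#' the disorder coefficient on the log2 scale (case vs control). Genes
#' whose optimizer fails to converge are flagged and excluded from the
#' FDR adjustment by [filterAndAdjust()].
#'
#' @param counts genes x samples count matrix (all cohort samples or a
#'   superset of the contrast).
#' @param samples sample metadata with `sample_id`, `diagnosis` and the
#'   covariate columns.
#' @param contrast length-2 character vector `c(case, control)`.
#' @param covariates covariate column names entering both designs
#'   (default `c("age", "pH", "PMI", "PRUA")`).
#' @param sizeFactors,dispersions optional precomputed values (computed
#'   from the contrast's samples when missing).
#' @param dispersionShrink passed to [estimateDispersionsMoM()].
#' @return a [DETable] (with `padj` unset; apply [filterAndAdjust()]).
#' @export
nbLRT <- function(counts, samples, contrast,
                  covariates = c("age", "pH", "PMI", "PRUA"),
                  sizeFactors = NULL, dispersions = NULL,
                  dispersionShrink = 0.7) {
  if (length(contrast) != 2L) fail("contrast must be c(case, control)")
  if (!all(contrast %in% samples$diagnosis))
    fail("both contrast levels must be present in the cohort")
  keep <- samples$diagnosis %in% contrast
  samples <- samples[keep, , drop = FALSE]
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (!all(covariates %in% colnames(samples)))
    fail("missing covariate column(s): ",
         paste(setdiff(covariates, colnames(samples)), collapse = ", "))
  if (anyNA(samples[, covariates])) fail("incomplete covariates")

  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  disorder <- factor(samples$diagnosis, levels = rev(contrast))
  if (is.null(dispersions))
    dispersions <- estimateDispersionsMoM(counts, disorder, sizeFactors,
                                          shrink = dispersionShrink)
  Xr <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data = samples)
    else matrix(1, nrow(samples), 1L, dimnames = list(NULL, "(Intercept)"))
  Xf <- cbind(Xr, disorder = as.numeric(disorder == contrast[1L]))
  checkFullRank(Xf)
  off <- log(sizeFactors)
  baseMean <- rowMeans(sweep(counts, 2L, sizeFactors, "/"))

  n <- nrow(counts)
  pv <- rep(NA_real_, n); lfc <- rep(NA_real_, n)
  conv <- rep(FALSE, n)
  for (g in seq_len(n)) {
    a <- dispersions[g]
    y <- counts[g, ]
    if (is.na(a) || all(y == 0)) next
    res <- tryCatch({
      ff <- fitNbGlm(Xf, y, off, a)
      fr <- fitNbGlm(Xr, y, off, a)
      lrt <- 2 * (ff$logLik - fr$logLik)
      ok <- ff$converged && fr$converged && lrt > -1e-6
      list(p = stats::pchisq(max(lrt, 0), df = 1L, lower.tail = FALSE),
           lfc = ff$coef[["disorder"]] / log(2), ok = ok)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      pv[g] <- res$p; lfc[g] <- res$lfc; conv[g] <- res$ok
    }
  }
  DETable(gene_id = rownames(counts), baseMean = baseMean,
          log2FC = lfc, dispersion = as.numeric(dispersions),
          pvalue = pv, padj = rep(NA_real_, n), converged = conv)
}

#' Independent filtering and FDR adjustment
#'
#' Excludes genes below the base-mean threshold (and non-convergent
#' genes) from the Benjamini-Hochberg adjustment — their `padj` stays
#' `NA` — and adjusts the remaining p-values.
#'
#' @param de a [DETable].
#' @param minBaseMean minimum normalized mean count (default 10).
#' @return the [DETable] with `padj` filled in.
#' @export
filterAndAdjust <- function(de, minBaseMean = 10) {
  stopifnot(is(de, "DETable"))
  use <- !is.na(de$pvalue) & de$converged & de$baseMean >= minBaseMean
  padj <- rep(NA_real_, nrow(de))
  padj[use] <- bhAdjust(de$pvalue[use])
  df <- as(de, "DFrame")
  df$padj <- padj
  new("DETable", df)
}

#' Cross-disorder concordance of differential expression
#'
#' Over the shared gene universe, computes the Spearman correlation of
#' log2 fold changes between two contrasts, the counts of genes below an
#' uncorrected p-value threshold in each and in both, and a
#' hypergeometric (Fisher) overlap test of the two significant sets.
#'
#' @param deA,deB [DETable]s sharing gene identifiers.
#' @param pThreshold uncorrected significance cutoff (default 0.05).
#' @return list with `rho`, `rhoP`, `nShared`, `nA`, `nB`, `nBoth` and
#'   `overlap` (the [overlapTest()] result).
#' @export
crossdisorderConcordance <- function(deA, deB, pThreshold = 0.05) {
  shared <- intersect(deA$gene_id, deB$gene_id)
  if (!length(shared)) fail("no shared genes between the two tables")
  ia <- match(shared, deA$gene_id); ib <- match(shared, deB$gene_id)
  ok <- !is.na(deA$pvalue[ia]) & !is.na(deB$pvalue[ib])
  ia <- ia[ok]; ib <- ib[ok]
  sp <- spearmanCor(deA$log2FC[ia], deB$log2FC[ib])
  sa <- deA$pvalue[ia] < pThreshold
  sb <- deB$pvalue[ib] < pThreshold
  ov <- overlapTest(sum(sa & sb), sum(sa), sum(sb), length(ia),
                    method = "fisher")
  list(rho = sp$rho, rhoP = sp$p.value, nShared = length(ia),
       nA = sum(sa), nB = sum(sb), nBoth = sum(sa & sb), overlap = ov)
}
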