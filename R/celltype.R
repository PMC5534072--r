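# Marker-gene cell-type composition indices, in-silico count mixing and
# the two null-resampling enrichment schemes used to validate them.

#' Median-marker cell-type indices
#'
#' The index of a cell type in a sample is the median normalized
#' expression of that type's marker genes in the sample. Markers absent
#' from the matrix are dropped with a warning; a cell type losing all
#' markers is an error.
#'
#' @param norm a [NormalizedExpression] or genes x samples matrix.
#' @param signature named list: cell type -> marker gene ids.
#' @return samples x cell types numeric matrix of index values.
#' @export
computeIndex <- function(norm, signature) {
  v <- if (is(norm, "NormalizedExpression")) exprValues(norm) else norm
  if (!length(signature) || is.null(names(signature)))
    fail("signature must be a named list of marker sets")
  out <- matrix(NA_real_, ncol(v), length(signature),
                dimnames = list(colnames(v), names(signature)))
  for (ct in names(signature)) {
    present <- intersect(signature[[ct]], rownames(v))
    missing <- setdiff(signature[[ct]], rownames(v))
    if (length(missing))
      warning(sprintf("%d marker(s) of '%s' absent from matrix; dropped",
                      length(missing), ct))
    if (!length(present))
      fail("no marker of cell type '", ct, "' present in the matrix")
    out[, ct] <- apply(v[present, , drop = FALSE], 2L, stats::median)
  }
  out
}

#' Down-sample a count vector without replacement
#'
#' Draws `targetTotal` reads from the reads represented by `x` without
#' replacement (multivariate hypergeometric, realized by sequential
#' conditional hypergeometric draws), so the result sums to exactly
#' `targetTotal` and never exceeds the input elementwise.
#'
#' @param x non-negative integer count vector.
#' @param targetTotal number of reads to keep, between 0 and `sum(x)`.
#' @param seed integer seed.
#' @return integer vector, same length and names as `x`.
#' @export
downsampleCounts <- function(x, targetTotal, seed = NULL) {
  if (any(x < 0) || any(x != round(x))) fail("counts must be non-negative integers")
  total <- sum(x)
  assertScalarNumber(targetTotal, "targetTotal", lower = 0)
  if (targetTotal > total)
    fail("targetTotal exceeds the available ", total, " reads")
  if (targetTotal == total) return(x)
  withSeed(seed, {
    out <- integer(length(x))
    remaining <- total
    k <- targetTotal
    for (i in seq_along(x)) {
      if (k == 0) break
      d <- stats::rhyper(1L, m = x[i], n = remaining - x[i], k = k)
      out[i] <- d
      k <- k - d
      remaining <- remaining - x[i]
    }
    names(out) <- names(x)
    stopifnot(sum(out) == targetTotal, all(out <= x))
    out
  })
}

#' Mix purified count vectors in silico
#'
#' Each purified vector is down-sampled to `round(weight * commonTotal)`
#' reads and the results are summed gene-wise, yielding a pseudo-bulk
#' sample with known composition. With purified libraries of 5,759,178
#' reads and weights 0.8/0.2 the component targets are 4,607,342 and
#' 1,151,836 reads.
#'
#' @param pureCounts named list of count vectors sharing gene order.
#' @param weights non-negative weights summing to 1, one per vector.
#' @param commonTotal total to which each purified library is assumed
#'   equalized; defaults to the minimum library size.
#' @param seed integer seed.
#' @return list with `counts` (the mixed vector) and `targets` (the
#'   per-component read targets).
#' @export
mixInSilico <- function(pureCounts, weights, commonTotal = NULL,
                        seed = NULL) {
  if (length(pureCounts) != length(weights))
    fail("one weight per purified vector required")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    fail("weights must be non-negative and sum to 1")
  gn <- names(pureCounts[[1L]])
  for (v in pureCounts) {
    if (!identical(names(v), gn)) fail("purified vectors must share gene order")
  }
  if (is.null(commonTotal))
    commonTotal <- min(vapply(pureCounts, sum, numeric(1L)))
  targets <- round(weights * commonTotal)
  withSeed(seed, {
    mixed <- Reduce(`+`, Map(function(v, t) downsampleCounts(v, t),
                             pureCounts, targets))
    names(mixed) <- gn
    list(counts = mixed, targets = stats::setNames(targets,
                                                   names(pureCounts)))
  })
}

#' Predict a cell proportion from index values
#'
#' Predicted proportion = observed index / purified-tissue index, under
#' the assumption that the index scales linearly with the mixing weight.
#' Both indices must be computed on the same normalization. The raw
#' ratio is returned unclamped alongside a \[0, 1\]-clamped view.
#'
#' @param observedIndex index value(s) in the mixed sample(s).
#' @param purifiedIndex index value of the purified reference (> 0).
#' @return list with `estimate` (raw ratio) and `clamped`.
#' @export
predictProportion <- function(observedIndex, purifiedIndex) {
  if (!is.numeric(purifiedIndex) || any(purifiedIndex <= 0))
    fail("purified index must be positive")
  est <- observedIndex / purifiedIndex
  list(estimate = est, clamped = pmin(pmax(est, 0), 1))
}

#' Size-matched null gene sets for index accuracy
#'
#' Measures how well a marker set predicts known in-silico mixing
#' weights (mean squared error of index-ratio predictions over the
#' mixtures) and compares it with `nNull` random gene sets of the same
#' size drawn from the expressed genes. The empirical p-value uses the
#' add-one convention `(1 + #{null MSE <= observed}) / (nNull + 1)`.
#'
#' @param mixNorm genes x mixtures matrix of normalized expression of
#'   the in-silico mixtures.
#' @param pureNorm named numeric vector: normalized expression of the
#'   purified reference sample for the focal cell type (same genes).
#' @param trueWeights known mixing weight of the focal type per mixture.
#' @param markers the focal cell type's marker genes.
#' @param nNull number of null sets (>= 100).
#' @param seed integer seed.
#' @return list with `observedMSE`, `nullMSE` (length `nNull`) and
#'   `p.value`.
#' @export
nullIndexMSE <- function(mixNorm, pureNorm, trueWeights, markers,
                         nNull = 1000L, seed = NULL) {
  if (nNull < 100L) fail("nNull must be at least 100")
  if (length(trueWeights) != ncol(mixNorm))
    fail("one true weight per mixture required")
  markers <- intersect(markers, rownames(mixNorm))
  if (!length(markers)) fail("no marker present in the mixture matrix")
  expressed <- rownames(mixNorm)[rowMeans(mixNorm) > 0]
  if (length(expressed) < length(markers))
    fail("fewer expressed genes than the marker set size")
  setMSE <- function(g) {
    obs <- apply(mixNorm[g, , drop = FALSE], 2L, stats::median)
    pur <- stats::median(pureNorm[g])
    if (pur <= 0) return(Inf)
    mean((obs / pur - trueWeights)^2)
  }
  obsMSE <- setMSE(markers)
  nullMSE <- withSeed(seed, vapply(seq_len(nNull), function(i)
    setMSE(sample(expressed, length(markers))), numeric(1L)))
  list(observedMSE = obsMSE, nullMSE = nullMSE,
       p.value = (1 + sum(nullMSE <= obsMSE)) / (nNull + 1))
}

#' Expression-matched null gene sets for fold-change enrichment
#'
#' Tests whether a gene set's median log2 fold change is extreme
#' relative to `nNull` random sets matched gene-by-gene on expression
#' level: each null gene is drawn (without replacement within a null
#' set) from the genes whose baseMean lies within a relative tolerance
#' of the matched member's baseMean. Two-sided empirical p-value with
#' the add-one convention.
#'
#' @param de a [DETable].
#' @param geneSet member gene ids (must have baseMean and log2FC).
#' @param nNull number of null sets (default 1000).
#' @param exprTol relative baseMean tolerance (default 0.05, i.e. 5%).
#' @param onNoMatch `"error"` or `"widen"`: what to do when a member has
#'   no tolerance-window match (widening doubles the tolerance for that
#'   gene, with a warning).
#' @param returnNullSets also return the sampled null sets (row indices
#'   into `de`), for auditing the matching constraint.
#' @param seed integer seed.
#' @return list with `observed` (median log2FC), `null` (length
#'   `nNull`), `p.value`, and (optionally) `nullSets`.
#' @export
matchedNullFoldChange <- function(de, geneSet, nNull = 1000L,
                                  exprTol = 0.05,
                                  onNoMatch = c("error", "widen"),
                                  returnNullSets = FALSE,
                                  seed = NULL) {
  onNoMatch <- match.arg(onNoMatch)
  stopifnot(is(de, "DETable"))
  idx <- match(geneSet, de$gene_id)
  if (anyNA(idx)) fail("gene set member(s) missing from the DE table")
  ok <- !is.na(de$log2FC) & !is.na(de$baseMean)
  pool <- which(ok & !(de$gene_id %in% geneSet))
  bm <- de$baseMean
  candidates <- lapply(idx, function(i) {
    tol <- exprTol
    repeat {
      cand <- pool[abs(bm[pool] - bm[i]) <= tol * bm[i]]
      if (length(cand)) return(cand)
      if (onNoMatch == "error")
        fail("no expression-matched gene for ", de$gene_id[i],
             " within ", sprintf("%.1f%%", 100 * tol))
      tol <- tol * 2
      warning(sprintf("widened matching tolerance to %.1f%% for %s",
                      100 * tol, de$gene_id[i]))
    }
  })
  observed <- stats::median(de$log2FC[idx])
  sets <- withSeed(seed, lapply(seq_len(nNull), function(b) {
    used <- integer(0)
    vapply(candidates, function(cand) {
      free <- setdiff(cand, used)
      if (!length(free)) free <- cand  # fall back rather than abort
      p <- if (length(free) == 1L) free else sample(free, 1L)
      used <<- c(used, p)
      p
    }, integer(1L))
  }))
  null <- vapply(sets, function(s) stats::median(de$log2FC[s]),
                 numeric(1L))
  pLow <- (1 + sum(null <= observed)) / (nNull + 1)
  pHigh <- (1 + sum(null >= observed)) / (nNull + 1)
  out <- list(observed = observed, null = null,
              p.value = min(1, 2 * min(pLow, pHigh)))
  if (returnNullSets) out$nullSets <- sets
  out
}

#' Correlation of fold change with cell-type specificity
#'
#' Per gene, specificity is `log2(mean expression in the cell type /
#' mean over the other cell types)` from a reference panel; the result
#' is the Spearman correlation of case-control log2 fold changes with
#' this specificity (negative when the cell type's genes are
#' preferentially down in cases).
#'
#' @param de a [DETable].
#' @param panel a [CellProfilePanel] or genes x cell types matrix of
#'   reference mean expression.
#' @param cellType focal cell type (a panel column).
#' @param pseudocount added to both means before the ratio (default 0;
#'   genes with a zero denominator are dropped when 0).
#' @return list with `rho`, `p.value`, `n`.
#' @export
specificityCorrelation <- function(de, panel, cellType, pseudocount = 0) {
  m <- if (is(panel, "CellProfilePanel")) meanExpression(panel) else panel
  if (!cellType %in% colnames(m)) fail("unknown cell type: ", cellType)
  shared <- intersect(de$gene_id, rownames(m))
  if (length(shared) < 10L) fail("fewer than 10 shared genes")
  own <- m[shared, cellType] + pseudocount
  oth <- rowMeans(m[shared, setdiff(colnames(m), cellType),
                    drop = FALSE]) + pseudocount
  keep <- oth > 0 & own > 0
  spec <- log2(own[keep] / oth[keep])
  lfc <- de$log2FC[match(shared[keep], de$gene_id)]
  done <- !is.na(lfc)
  sp <- spearmanCor(lfc[done], spec[done])
  list(rho = sp$rho, p.value = sp$p.value, n = sum(done))
}

#' Constrained least-squares deconvolution
#'
#' Estimates per-sample cell-type weights by solving
#' `min || x - S w ||^2` subject to `w >= 0` and `sum(w) = 1`, the
#' standard reference-profile deconvolution used to cross-check the
#' index-ratio predictions.
#'
#' @param x genes x samples matrix (or vector) of mixture expression.
#' @param S genes x cell types reference profile matrix, full column
#'   rank on the shared genes.
#' @return samples x cell types weight matrix.
#' @export
lsDeconvolve <- function(x, S) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L,
                                dimnames = list(names(x), "sample1"))
  shared <- intersect(rownames(x), rownames(S))
  if (length(shared) < ncol(S)) fail("too few shared genes")
  S <- S[shared, , drop = FALSE]
  x <- x[shared, , drop = FALSE]
  if (qr(S)$rank < ncol(S)) fail("reference profile matrix is rank-deficient")
  sc <- mean(abs(S))  # joint rescaling: conditions the QP, same argmin
  w <- vapply(seq_len(ncol(x)), function(j) {
    pracma::lsqlincon(S / sc, x[, j] / sc,
                      Aeq = matrix(1, 1L, ncol(S)), beq = 1,
                      lb = rep(0, ncol(S)))
  }, numeric(ncol(S)))
  t(matrix(w, ncol(S), ncol(x),
           dimnames = list(colnames(S), colnames(x))))
}
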