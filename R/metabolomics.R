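# Metabolite-level differential statistics, top-metabolite clustering
# and the gene-metabolite ratio correlation analysis.

#' Per-metabolite differential abundance
#'
#' For one diagnosis pair, tests each metabolite with a two-sided
#' rank-sum test (rank-based, hence invariant to per-metabolite monotone
#' rescaling) and adjusts across metabolites with Benjamini-Hochberg.
#' Technical replicates, when a `subject` mapping is given, are averaged
#' per subject before testing. A metabolite constant across all samples
#' gets p = 1 and is flagged.
#'
#' @param metab metabolites x samples abundance matrix.
#' @param samples sample metadata with `sample_id` and `diagnosis`.
#' @param comparison length-2 character vector `c(case, control)`.
#' @param subject optional named vector mapping sample_id to subject id;
#'   technical replicates of a subject are averaged.
#' @param test `"wilcox"` (default) or `"t"`.
#' @return data.frame with `metabolite`, `p`, `fdr`, `medianCase`,
#'   `medianControl`, `flagged` (constant metabolites), sorted in input
#'   order.
#' @export
metabDiff <- function(metab, samples, comparison,
                      subject = NULL, test = c("wilcox", "t")) {
  test <- match.arg(test)
  if (length(comparison) != 2L) fail("comparison must be c(case, control)")
  keep <- samples$diagnosis %in% comparison
  samples <- samples[keep, , drop = FALSE]
  metab <- metab[, samples$sample_id, drop = FALSE]
  if (!is.null(subject)) {
    subj <- subject[samples$sample_id]
    agg <- t(apply(metab, 1L, function(x) tapply(x, subj, mean)))
    diagBySubj <- tapply(samples$diagnosis, subj, `[[`, 1L)
    metab <- agg
    groups <- diagBySubj[colnames(agg)]
  } else {
    groups <- samples$diagnosis
  }
  case <- groups == comparison[1L]
  if (sum(case) < 3L || sum(!case) < 3L)
    fail("need at least 3 samples per group")
  res <- t(apply(metab, 1L, function(x) {
    a <- x[case]; b <- x[!case]
    if (stats::sd(x) == 0)
      return(c(p = 1, mc = stats::median(a), mk = stats::median(b),
               flag = 1))
    p <- if (test == "wilcox") rankSumTest(a, b)$p.value
      else stats::t.test(a, b)$p.value
    c(p = p, mc = stats::median(a), mk = stats::median(b), flag = 0)
  }))
  data.frame(metabolite = rownames(metab), p = res[, "p"],
             fdr = bhAdjust(res[, "p"]),
             medianCase = res[, "mc"], medianControl = res[, "mk"],
             flagged = res[, "flag"] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cluster samples on the top metabolites of each comparison
#'
#' Takes the union of the `k` most significant metabolites of each
#' comparison (ties broken by metabolite id, lexicographically), log
#' transforms and row z-scores their abundances, and Ward-clusters the
#' samples on Euclidean distances.
#'
#' @param metab metabolites x samples abundance matrix.
#' @param results list of [metabDiff()] data.frames, one per comparison.
#' @param k metabolites per comparison (default 10).
#' @param nClusters flat clusters to cut (default 2).
#' @param logTransform log the abundances (with a +1 offset) before
#'   z-scoring (default TRUE).
#' @return list with `selected` (metabolite ids), `labels` (per-sample
#'   cluster), `hclust`.
#' @export
topKClustering <- function(metab, results, k = 10L, nClusters = 2L,
                           logTransform = TRUE) {
  if (length(results) < 2L) fail("need at least two comparisons")
  selected <- unique(unlist(lapply(results, function(r) {
    kk <- min(k, nrow(r))
    if (kk < k) warning("fewer metabolites than k; taking all")
    r$metabolite[order(r$p, r$metabolite)][seq_len(kk)]
  })))
  x <- metab[selected, , drop = FALSE]
  if (logTransform) x <- log(x + 1)
  z <- zscoreRows(x)
  cl <- wardCluster(t(z), k = nClusters)
  list(selected = selected, labels = cl$labels, hclust = cl$hclust)
}

#' Metabolite-ratio vs gene-expression correlation
#'
#' Per sample, forms the ratio of two metabolite abundances and
#' correlates it (Spearman) with the mean normalized expression of a
#' gene pair — the analysis relating the GABA:glutamate ratio to mean
#' GAD1/GAD2 expression. Samples with a non-positive denominator are
#' dropped with a message.
#'
#' @param metab metabolites x samples abundance matrix.
#' @param numeratorId,denominatorId metabolite ids.
#' @param norm a [NormalizedExpression] or genes x samples matrix.
#' @param geneIds character vector of predictor genes (typically 2).
#' @return list with `rho`, `p.value`, `n`, `defined`.
#' @export
ratioCorrelation <- function(metab, numeratorId, denominatorId, norm,
                             geneIds) {
  v <- if (is(norm, "NormalizedExpression")) exprValues(norm) else norm
  for (id in c(numeratorId, denominatorId)) {
    if (!id %in% rownames(metab)) fail("metabolite not measured: ", id)
  }
  if (!all(geneIds %in% rownames(v)))
    fail("gene(s) missing from expression matrix: ",
         paste(setdiff(geneIds, rownames(v)), collapse = ", "))
  shared <- intersect(colnames(metab), colnames(v))
  if (length(shared) < 3L) fail("fewer than 3 shared samples")
  num <- metab[numeratorId, shared]
  den <- metab[denominatorId, shared]
  ok <- den > 0
  if (any(!ok)) message(sum(!ok), " sample(s) dropped: zero denominator")
  ratio <- num[ok] / den[ok]
  pred <- colMeans(v[geneIds, shared, drop = FALSE])[ok]
  sp <- spearmanCor(ratio, pred)
  list(rho = sp$rho, p.value = sp$p.value, n = sp$n,
       defined = sp$defined)
}
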