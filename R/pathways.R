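# Threshold-free integrated pathway enrichment: one-tailed Wilcoxon
# rank tests of member p-values against the non-member background in
# each omics layer, combined across layers by Fisher's method.

#' Rank-based one-tailed enrichment for low p-values
#'
#' Ranks all features by p-value (mid-ranks for ties) and tests, with a
#' one-tailed rank-sum test, whether the member features occupy lower
#' ranks (smaller p-values) than the non-member background. Being
#' rank-based, the result is invariant to any strictly monotone
#' transform of the input p-values.
#'
#' @param featureP named numeric vector of per-feature p-values.
#' @param members feature ids forming the set; must leave at least one
#'   background feature.
#' @return one-tailed enrichment p-value.
#' @export
rankWilcoxEnrich <- function(featureP, members) {
  if (is.null(names(featureP))) fail("featureP must be named")
  featureP <- featureP[!is.na(featureP)]
  inSet <- names(featureP) %in% members
  if (!any(inSet)) fail("no member with a defined p-value")
  if (all(inSet)) fail("members cover all features: no background")
  rankSumTest(featureP[inSet], featureP[!inSet], tail = "lower")$p.value
}

#' Fisher's method for two p-values
#'
#' `X = -2 (ln pA + ln pB)` referred to the upper tail of a chi-square
#' distribution with 4 degrees of freedom. Zero inputs are clamped to
#' the smallest representable positive double with a warning.
#'
#' @param pA,pB p-values in (0, 1].
#' @return combined p-value.
#' @export
fisherCombine <- function(pA, pB) {
  for (v in c("pA", "pB")) {
    p <- get(v)
    assertScalarNumber(p, v, lower = 0, upper = 1)
  }
  if (pA == 0 || pB == 0) {
    warning("zero p-value clamped to the smallest positive double")
    pA <- max(pA, .Machine$double.xmin)
    pB <- max(pB, .Machine$double.xmin)
  }
  x <- -2 * (log(pA) + log(pB))
  stats::pchisq(x, df = 4L, lower.tail = FALSE)
}

#' Integrated gene + metabolite pathway enrichment
#'
#' Pathways must contain more than five measured genes and at least one
#' measured metabolite to enter the analysis. For each surviving
#' pathway, the gene layer and the metabolite layer are scored by
#' [rankWilcoxEnrich()] against their respective backgrounds (all
#' measured non-member features), the two layer p-values are combined by
#' [fisherCombine()], and the combined p-values are BH-adjusted across
#' the surviving pathways.
#'
#' @param de a [DETable]; the gene layer uses its uncorrected p-values.
#' @param metabP named numeric vector of per-metabolite p-values.
#' @param pathways named list as from [readPathwayGmt()]: each element
#'   holds `genes` and `metabolites` member vectors.
#' @param minGenes minimum measured gene members (default 6, i.e.
#'   strictly more than five).
#' @param minMetabs minimum measured metabolite members (default 1).
#' @return data.frame with one row per surviving pathway, in input
#'   order: `pathway`, `n_genes`, `n_metabolites`, `p_gene`,
#'   `p_metabolite`, `p_combined`, `padj_combined`.
#' @export
integratedEnrichment <- function(de, metabP, pathways, minGenes = 6L,
                                 minMetabs = 1L) {
  stopifnot(is(de, "DETable"))
  geneP <- stats::setNames(de$pvalue, de$gene_id)
  geneP <- geneP[!is.na(geneP)]
  metabP <- metabP[!is.na(metabP)]
  rows <- list()
  for (id in names(pathways)) {
    pw <- pathways[[id]]
    ng <- sum(names(geneP) %in% pw$genes)
    nm <- sum(names(metabP) %in% pw$metabolites)
    if (ng < minGenes || nm < minMetabs) next
    rows[[id]] <- data.frame(
      pathway = id, n_genes = ng, n_metabolites = nm,
      p_gene = rankWilcoxEnrich(geneP, pw$genes),
      p_metabolite = rankWilcoxEnrich(metabP, pw$metabolites),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(pathway = character(), n_genes = integer(),
                      n_metabolites = integer(), p_gene = numeric(),
                      p_metabolite = numeric(), p_combined = numeric(),
                      padj_combined = numeric()))
  }
  out <- do.call(rbind, rows)
  out$p_combined <- mapply(fisherCombine, out$p_gene, out$p_metabolite)
  out$padj_combined <- bhAdjust(out$p_combined)
  rownames(out) <- NULL
  out
}
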