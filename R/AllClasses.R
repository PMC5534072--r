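#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Normalized expression matrix with provenance
#'
#' Container for a genes-by-samples matrix of normalized expression values
#' together with the per-sample size factors used to produce it and an
#' ordered record of the transforms applied (`"log_like"`,
#' `"residualized"`, `"zscored"`).
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot sizeFactors positive numeric vector, one entry per sample.
#' @slot transforms character vector naming the transforms applied, in
#'   application order.
#'
#' @seealso [logLikeTransform()], [residualize()]
#' @export
setClass("NormalizedExpression",
  representation(values = "matrix",
                 sizeFactors = "numeric",
                 transforms = "character"))

setValidity("NormalizedExpression", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry gene and sample names")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
  if (length(object@sizeFactors) != ncol(v))
    msg <- c(msg, "one size factor per sample required")
  if (any(!is.finite(object@sizeFactors)) || any(object@sizeFactors <= 0))
    msg <- c(msg, "size factors must be positive and finite")
  ok <- c("log_like", "residualized", "zscored")
  if (!all(object@transforms %in% ok))
    msg <- c(msg, sprintf("transforms must be among: %s",
                          paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @describeIn NormalizedExpression constructor.
#' @param values,sizeFactors,transforms see slots.
#' @export
NormalizedExpression <- function(values, sizeFactors,
                                 transforms = character()) {
  new("NormalizedExpression", values = values,
      sizeFactors = as.numeric(sizeFactors), transforms = transforms)
}

#' @describeIn NormalizedExpression the normalized matrix.
#' @param x a `NormalizedExpression`.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "NormalizedExpression"))
  x@values
}

#' @describeIn NormalizedExpression per-sample size factors.
#' @export
sampleSizeFactors <- function(x) {
  stopifnot(is(x, "NormalizedExpression"))
  x@sizeFactors
}

#' @describeIn NormalizedExpression ordered transform provenance.
#' @export
transforms <- function(x) {
  stopifnot(is(x, "NormalizedExpression"))
  x@transforms
}

setMethod("show", "NormalizedExpression", function(object) {
  cat(sprintf("NormalizedExpression: %d genes x %d samples\n",
              nrow(object@values), ncol(object@values)))
  cat("  transforms:",
      if (length(object@transforms)) paste(object@transforms,
                                           collapse = " -> ") else "(none)",
      "\n")
})

#' Per-gene differential expression table
#'
#' A `DataFrame` subclass with the fixed column set produced by [nbLRT()]:
#' `gene_id`, `baseMean`, `log2FC`, `dispersion`, `pvalue`, `padj`,
#' `converged`.
#'
#' @export
setClass("DETable", contains = "DFrame")

deTableColumns <- c("gene_id", "baseMean", "log2FC", "dispersion",
                    "pvalue", "padj", "converged")

setValidity("DETable", function(object) {
  msg <- character()
  if (!all(deTableColumns %in% colnames(object)))
    msg <- c(msg, sprintf("required columns: %s",
                          paste(deTableColumns, collapse = ", ")))
  else {
    if (anyDuplicated(object$gene_id)) msg <- c(msg, "duplicate gene ids")
    p <- object$pvalue; q <- object$padj
    bad <- !is.na(p) & !is.na(q) & q < p - 1e-12
    if (any(bad)) msg <- c(msg, "padj must be >= pvalue")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DETable construct a `DETable` from per-gene vectors.
#' @param gene_id,baseMean,log2FC,dispersion,pvalue,padj,converged columns.
#' @export
DETable <- function(gene_id, baseMean, log2FC, dispersion, pvalue,
                    padj = rep(NA_real_, length(gene_id)),
                    converged = rep(TRUE, length(gene_id))) {
  new("DETable", DataFrame(gene_id = as.character(gene_id),
                           baseMean = as.numeric(baseMean),
                           log2FC = as.numeric(log2FC),
                           dispersion = as.numeric(dispersion),
                           pvalue = as.numeric(pvalue),
                           padj = as.numeric(padj),
                           converged = as.logical(converged)))
}

#' Reference expression panel over brain cell types
#'
#' Per-gene mean expression profiles for a panel of cell types together
#' with disjoint marker-gene sets. Markers satisfy a specificity
#' constraint: mean expression in their own cell type is at least
#' `specificityFold` times the maximum mean in any other type.
#'
#' @slot meanExpression positive matrix, genes x cell types.
#' @slot markers named list of marker gene id vectors, one per cell type.
#' @slot specificityFold the fold threshold the markers satisfy.
#' @export
setClass("CellProfilePanel",
  representation(meanExpression = "matrix",
                 markers = "list",
                 specificityFold = "numeric"))

setValidity("CellProfilePanel", function(object) {
  msg <- character()
  m <- object@meanExpression
  if (ncol(m) < 2L) msg <- c(msg, "at least two cell types required")
  if (any(m <= 0)) msg <- c(msg, "mean expression must be positive")
  if (!identical(sort(names(object@markers)), sort(colnames(m))))
    msg <- c(msg, "marker list names must match cell types")
  allm <- unlist(object@markers, use.names = FALSE)
  if (anyDuplicated(allm))
    msg <- c(msg, "marker sets must be disjoint across cell types")
  if (!all(allm %in% rownames(m)))
    msg <- c(msg, "markers must be genes of the panel")
  fold <- object@specificityFold
  for (ct in names(object@markers)) {
    g <- object@markers[[ct]]
    if (length(g) == 0L) next
    own <- m[g, ct]
    oth <- apply(m[g, setdiff(colnames(m), ct), drop = FALSE], 1L, max)
    if (any(own < fold * oth - 1e-8))
      msg <- c(msg, sprintf("marker specificity below %.3g-fold for '%s'",
                            fold, ct))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CellProfilePanel cell-type names.
#' @param x a `CellProfilePanel`.
#' @export
cellTypes <- function(x) {
  stopifnot(is(x, "CellProfilePanel"))
  colnames(x@meanExpression)
}

#' @describeIn CellProfilePanel marker gene sets (named list).
#' @export
markerSets <- function(x) {
  stopifnot(is(x, "CellProfilePanel"))
  x@markers
}

#' @describeIn CellProfilePanel genes x cell types mean expression matrix.
#' @export
meanExpression <- function(x) {
  stopifnot(is(x, "CellProfilePanel"))
  x@meanExpression
}

setMethod("show", "CellProfilePanel", function(object) {
  cat(sprintf("CellProfilePanel: %d genes, %d cell types (%s)\n",
              nrow(object@meanExpression), ncol(object@meanExpression),
              paste(colnames(object@meanExpression), collapse = ", ")))
  cat(sprintf("  markers: %s; specificity fold >= %.3g\n",
              paste(vapply(object@markers, length, 1L), collapse = "/"),
              object@specificityFold))
})
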