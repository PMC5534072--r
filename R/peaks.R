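# Consensus ChIP-seq peak construction across replicate peak sets and
# the TSS-distance threshold sweep relating peak proximity to
# differential expression.

#' @importFrom GenomicRanges findOverlaps distanceToNearest seqnames start end
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Consensus peaks across replicate peak sets
#'
#' `mode = "anchored"` (default) keeps the intervals of the FIRST set
#' that overlap by at least `minOverlap` bp with at least one interval
#' in EVERY other set — the chained `bedtools intersect -u` semantics,
#' which returns peaks drawn from a reference list. `mode = "region"`
#' instead intersects the covered regions of all sets and keeps pieces
#' of width at least `minOverlap`.
#'
#' @param peakSets list of at least two `GRanges`.
#' @param minOverlap minimum overlap in bp (default 1).
#' @param mode `"anchored"` or `"region"`.
#' @return `GRanges` sorted by (chrom, start).
#' @export
consensusPeaks <- function(peakSets, minOverlap = 1L,
                           mode = c("anchored", "region")) {
  mode <- match.arg(mode)
  if (length(peakSets) < 2L) fail("at least two peak sets required")
  if (length(peakSets[[1L]]) == 0L) {
    warning("first peak set is empty; consensus is empty")
    return(peakSets[[1L]])
  }
  if (mode == "anchored") {
    anchor <- peakSets[[1L]]
    keep <- rep(TRUE, length(anchor))
    for (other in peakSets[-1L]) {
      hits <- findOverlaps(anchor, other, minoverlap = minOverlap)
      keep <- keep & seq_along(anchor) %in% queryHits(hits)
    }
    sort(anchor[keep])
  } else {
    out <- Reduce(GenomicRanges::intersect, peakSets)
    sort(out[GenomicRanges::width(out) >= minOverlap])
  }
}

#' Distance from each TSS to the nearest peak
#'
#' Distance is 0 when the TSS base lies inside a peak, otherwise the
#' number of bases strictly between the TSS and the nearest peak edge on
#' the same chromosome (unstranded). Genes on chromosomes without any
#' peak get `NA` and are excluded downstream.
#'
#' @param tss TSS table as from [readTss()] (columns `gene_id`, `chrom`,
#'   `tss` 0-based, `strand`).
#' @param peaks `GRanges` of peaks.
#' @return named numeric vector of distances in bp, one per gene.
#' @export
nearestPeakDistance <- function(tss, peaks) {
  if (length(peaks) == 0L) fail("empty peak list")
  gr <- tssAsGRanges(tss)
  hits <- distanceToNearest(gr, peaks, ignore.strand = TRUE)
  d <- rep(NA_real_, length(gr))
  d[queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  stats::setNames(d, tss$gene_id)
}

#' TSS proximity threshold sweep
#'
#' At each distance threshold `t`, genes with a defined peak distance
#' are split into near (`distance <= t`) and far sets, and two one-tailed
#' rank-sum tests are run: `p_de` tests that near genes have LOWER
#' differential-expression p-values than far genes (stronger
#' dysregulation near peaks) and `p_expr` tests that near genes have
#' lower case-vs-control log2 fold changes (reduced expression near
#' peaks). A threshold with an empty side is reported with `NA`
#' p-values.
#'
#' @param de a [DETable].
#' @param distances named per-gene distances from
#'   [nearestPeakDistance()].
#' @param thresholds ascending distance thresholds in bp (default 1, 2,
#'   5, 10, 20 and 50 kb).
#' @return data.frame with columns `threshold`, `n_near`, `n_far`,
#'   `p_de`, `p_expr`; `n_near` is non-decreasing in threshold.
#' @export
proximitySweep <- function(de, distances,
                           thresholds = c(1, 2, 5, 10, 20, 50) * 1000) {
  stopifnot(is(de, "DETable"))
  if (is.unsorted(thresholds, strictly = TRUE))
    fail("thresholds must be strictly ascending")
  idx <- match(names(distances), de$gene_id)
  ok <- !is.na(idx) & !is.na(distances)
  d <- distances[ok]
  p <- de$pvalue[idx[ok]]
  lfc <- de$log2FC[idx[ok]]
  def <- !is.na(p) & !is.na(lfc)
  d <- d[def]; p <- p[def]; lfc <- lfc[def]
  rows <- lapply(thresholds, function(t) {
    near <- d <= t
    nNear <- sum(near); nFar <- sum(!near)
    if (nNear == 0L || nFar == 0L) {
      return(data.frame(threshold = t, n_near = nNear, n_far = nFar,
                        p_de = NA_real_, p_expr = NA_real_))
    }
    data.frame(threshold = t, n_near = nNear, n_far = nFar,
               p_de = rankSumTest(p[near], p[!near],
                                  tail = "lower")$p.value,
               p_expr = rankSumTest(lfc[near], lfc[!near],
                                    tail = "lower")$p.value)
  })
  out <- do.call(rbind, rows)
  stopifnot(!is.unsorted(out$n_near))
  out
}
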