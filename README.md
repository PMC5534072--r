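# neuromix

Downstream analysis toolkit for case/control multi-omics studies of
post-mortem brain tissue (bulk RNA-seq counts plus metabolite
abundances, with sample-level covariates such as age, brain pH,
post-mortem interval and the percentage of uniquely aligned reads,
PRUA). It is written for analysts who need the bespoke statistical
machinery of such studies as tested, reusable components rather than
one-off scripts:

* **Covariate-aware differential expression** — per-gene
  negative-binomial GLMs with size-factor offsets, comparing the full
  design `~ age + pH + PMI + PRUA + disorder` against the nested
  covariate-only design by a likelihood-ratio test,
  `2(ℓ_full − ℓ_reduced) ~ χ²(1)`, with method-of-moments dispersions
  shrunk toward an `a₀ + a₁/μ` trend, base-mean independent filtering
  and Benjamini–Hochberg FDR.
* **Cell-type composition indices** — the index of cell type *t* in
  sample *s* is the median normalized expression of *t*'s marker genes
  in *s*; proportions are predicted as
  `observed index / purified-tissue index`, validated by in-silico
  mixing: purified count vectors are down-sampled without replacement
  (multivariate hypergeometric) to weight-proportional read targets and
  summed. Two null-resampling schemes (size-matched random gene sets;
  expression-matched sets within 5% on base mean) quantify how special
  the marker sets are, and a constrained least-squares deconvolution
  (`min ‖x − S w‖²`, `w ≥ 0`, `Σw = 1`) cross-checks the index ratios.
* **Consensus ChIP-seq peaks and TSS proximity sweeps** — peaks of a
  reference set supported (≥ 1 bp overlap) in every replicate set;
  distance from each TSS to the nearest consensus peak; one-tailed
  rank-sum tests of near-vs-far genes swept over 1–50 kb thresholds.
* **Integrated pathway enrichment** — per omics layer, a one-tailed
  Wilcoxon rank test of member p-values against the non-member
  background; gene and metabolite layer p-values combined by Fisher's
  method (`−2(ln p_g + ln p_m) ~ χ²(4)`); pathways require more than
  five measured genes and at least one measured metabolite.
* **Metabolomics** — rank-based differential abundance with FDR,
  top-k metabolite Ward clustering, and metabolite-ratio vs
  gene-expression Spearman correlations (e.g. GABA:glutamate against
  mean GAD1/GAD2 expression).
* **A synthetic cohort generator with planted ground truth** —
  cell-type mixing weights, disorder effects, peak-proximal
  transcription-factor effects, PRUA-driven count thinning and
  gene–metabolite couplings are all planted and recorded, so every
  stage above is benchmarked against known truth without any
  restricted data.

## Worked example

```r
library(neuromix)

cfg <- cohortConfig(groupSizes = c(CTL = 12L, SZ = 12L, BPD = 0L, MDD = 0L),
                    nGenes = 1000L, nDEGenes = c(SZ = 40L))
cohort <- makeCohort(cfg, seed = 2)

norm <- normalizePipeline(cohort$counts, covariate = cohort$samples$PRUA)
norm
#> NormalizedExpression: 1000 genes x 24 samples
#>   transforms: log_like -> residualized

de <- filterAndAdjust(nbLRT(cohort$counts, cohort$samples, c("SZ", "CTL")))
sum(de$padj < 0.05, na.rm = TRUE)
#> 66   # of 941 genes passing the base-mean filter

planted <- names(cohort$truth$disorderEffects$SZ)
sum(de$gene_id[which(de$padj < 0.05)] %in% planted)
#> 39   # 39 of the 40 planted log2FC = +/-1 genes are recovered; the
#>      # remaining hits ride on the planted neuron-composition shift

idx <- computeIndex(norm, markerSets(cohort$panel))
head(round(idx, 2), 3)
#>      neuron astrocyte oligodendrocyte microglia
#> S001   9.57      9.31            9.06      8.68
#> S002   9.39      9.35            9.00      8.51
#> S003   9.36      9.18            8.88      8.28

sz <- cohort$samples$diagnosis == "SZ"
rankSumTest(idx[sz, "neuron"], idx[!sz, "neuron"], tail = "lower")$p.value
#> 0.00969   # the planted neuron-weight loss in SZ is visible in the index
```

The numbers mean: with a planted neuron-weight shift of −0.10 and 40
planted per-gene effects, the NB-LRT recovers nearly all planted genes
at FDR < 0.05, and the marker-median index detects the composition
shift by a one-tailed rank-sum test.

A command-line driver covers the same pipeline end to end
(`simulate → normalize → de → celltype → peaks → metab → pathways`):

```sh
Rscript inst/scripts/neuromix all --config config.yml --seed 7 --outdir out/
```

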