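---
title: "neuromix: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuromix: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromix)
```

neuromix re-implements, as reusable and tested components, the downstream
analyses used in case/control multi-omics studies of post-mortem brain
tissue: covariate-aware differential expression of bulk RNA-seq counts,
marker-gene cell-type composition indices validated by in-silico count
mixing, null gene-set resampling, consensus ChIP-seq peak / TSS proximity
statistics, and integrated gene + metabolite pathway enrichment. Because
the patient cohorts such studies rest on are access-restricted, the
package ships a synthetic cohort generator with planted ground truth;
every claim the package makes about its methods is demonstrated against
that truth rather than against irreproducible data.

## The synthetic cohort generator

`makeCohort()` draws, for each sample, a vector of cell-type mixing
weights and composes its expected expression from per-cell-type
reference profiles (`makeProfiles()`), so that "differential expression"
in the default cohort arises mechanistically the way the field believes
it does in real tissue: largely through composition shifts, with
additional planted per-gene disorder effects.

* **Profiles.** Baseline per-gene means are log-normal
  (`meanlog = log(50)`, `sdlog = 1`), with mild per-cell-type variation
  (`sdlog = 0.15`). Each cell type gets a disjoint marker set whose mean
  in its own type is `specificityFold` times the maximum elsewhere. The
  default fold is 50: the marker sets this emulates are derived from
  single-cell studies that selected genes essentially exclusive to one
  cell type, and the index-ratio deconvolution below structurally
  assumes near-exclusivity — at a fold of `f`, a mixture with true
  neuron weight `w` has a predicted weight biased upward by roughly
  `(1 - w) / f`.
* **Mixing weights.** The control neuron weight is Beta-distributed
  with mean 0.45 (concentration 60); SZ and BPD means are shifted by
  −0.10 and −0.08, MDD is unshifted. The non-neuron weights split the
  remainder in fixed proportions (astrocyte 0.30 of baseline, and so
  on), so a neuron loss automatically appears as a relative astrocyte
  gain — the pattern reported in patient tissue. No effect-size scale is
  published for these shifts; the defaults were chosen once so that
  recovery tests at 10–24 samples per group are well powered, and are
  configurable.
* **Counts.** Negative-binomial with variance `mu + alpha mu^2` and a
  shared dispersion `alpha = 0.05`; `alpha = 0` degenerates to Poisson.
  Library size defaults to 200,000 expected reads over 2,000 genes —
  per-gene depth comparable to a 20M-read library over 20,000 genes, at
  desk-scale runtime.
* **PRUA distortion.** The percentage of reads uniquely aligned acts as
  a per-sample binomial thinning of the true counts, with retention
  proportional to PRUA (Beta with mean 0.85). Thinning mimics
  alignment-quality signal loss; it is exactly the kind of multiplicative
  technical effect that the normalization stage's residualization is
  meant to remove, and setting `pruaCaseShift` non-zero creates the
  diagnosis-correlated confounding used to show that modelling PRUA in
  the design suppresses false positives.
* **Peak-proximity effects.** `makeGenome()` places TSSs on one 10 Mb
  synthetic chromosome (long enough for a 50 kb proximity sweep) and
  plants a core peak list that appears, with ±`jitter` bp boundary
  noise, in all replicate peak sets, plus per-set private peaks. With a
  genome attached, `tfEffect` (log2) multiplies case-group expression of
  genes whose true distance to a core peak is at most `tfWindow`
  (default 1 kb), emulating loss of a transcription factor's activation.
* **Metabolites.** Coupled metabolites follow, on the log scale,
  `rho * z + noiseSd * sqrt(1 - rho^2) * e` where `z` is the
  standardized mean normalized expression of the source genes; at
  `noiseSd = 1` the log-scale correlation approaches `rho`, and as
  `noiseSd` tends to 0 it tends to 1. Abundances are exponentiated
  (log-normal, hence non-negative); because the coupling checks are
  rank-based, the exponentiation is harmless. Uncoupled metabolites are
  independent log-normal.

What the generator does **not** emulate: GC/length biases, outlier
samples, batch structure, agonal-state or medication effects (age, pH
and PMI are inert metadata), zero inflation, and correlated gene-gene
modules beyond the composition axis. Passing the planted-truth suites
therefore demonstrates the correctness and calibration of the
statistical machinery, not robustness to every artefact of real tissue.

## Normalization

The pipeline order is fixed: counts → median-of-ratios size factors →
`log2(count / sizeFactor + 1)` → per-gene OLS residualization on PRUA,
with provenance recorded on the `NormalizedExpression` object. The
log-shifted transform stands in for a spline-based variance-stabilizing
transform; the downstream consumers (medians, ranks, residuals,
Euclidean clustering) are insensitive to the difference between the two
monotone transforms at these depths, which is why the lighter transform
is the default. Residuals are re-centered at the gene mean so values
stay on an interpretable expression scale; after residualization every
gene's Pearson correlation with the covariate is zero to machine
precision. Row z-scores use the population (n) denominator; zero-spread
rows are set to 0 and flagged instead of producing NaN.

## Differential expression

`nbLRT()` is a deliberately transparent stand-in for a full
shrinkage-based NB pipeline. Per gene it fits log-link negative-binomial
GLMs with log size factors as offsets under the full design
(`~ age + pH + PMI + PRUA + disorder`) and the nested reduced design,
at a fixed dispersion, and refers `2 (llFull - llReduced)` to
chi-square(1). Dispersion comes from `estimateDispersionsMoM()`:
within-group method-of-moments `max(0, (s2 - mu) / mu^2)` (group-pooled
variance so real effects do not inflate it), shrunk 70% toward a fitted
`a0 + a1/mu` trend. The shrinkage weight is the method's stabilization
default: raw per-gene moments at n = 24 + 24 are noisy and biased low,
and the trend pull restores type-I error to ~0.04–0.06 at the 0.05
level in the null-cohort check. There is no Cox–Reid adjustment, no
outlier filtering, and no fold-change shrinkage; everything downstream
consumes only (`baseMean`, `log2FC`, `pvalue`, `padj`). Non-convergent
genes are flagged and excluded from the Benjamini–Hochberg adjustment,
as are genes below the `baseMean` threshold (default 10) in
`filterAndAdjust()` — a fixed-threshold form of independent filtering.
Each disorder is contrasted against controls separately as a two-level
factor; the alternative (one four-level factor) is not implemented
because every reported comparison is pairwise.

## Cell-type indices and their validation

The index of a cell type in a sample is the median normalized
expression of its marker genes. Two scales are involved, and the
package keeps them explicit rather than hiding the choice:

* For **cohort comparisons** (cases vs controls, z-scored displays) the
  index is computed on the log-like, PRUA-residualized values — the
  variance-stabilized scale on which medians are robust summaries.
* For **proportion prediction** (`predictProportion()`, the in-silico
  mixing validation) observed and purified indices must be computed on
  the same *linear* depth-normalized scale (e.g. counts per million):
  the prediction formula `observed / purified` assumes the index scales
  linearly with the mixing weight, which is false after a log
  transform.

`downsampleCounts()` draws reads without replacement (multivariate
hypergeometric, realized by sequential conditional `rhyper` draws), so
a down-sampled library sums exactly to its target — reproducing, for a
5,759,178-read library mixed 80:20, the component targets 4,607,342 and
1,151,836. Rounding of `weight * total` is to the nearest integer
precisely because that reproduces this printed pair. Empirical p-values
from both null-resampling schemes use the add-one convention
`(1 + k) / (1 + n)`, which cannot return zero from finite resampling.
Expression matching for `matchedNullFoldChange()` uses `baseMean` with
a 5% relative tolerance; members with an empty matching window either
abort or, when configured, double their tolerance with a warning. The
observed gene set itself is excluded from the matching pool, and
nothing else is: whether other cell types' markers should also be
excluded is not specified anywhere authoritative, and excluding only
the observed set is the more conservative null. `lsDeconvolve()`
(non-negative, sum-to-one least squares via `pracma::lsqlincon`) is the
independent cross-check on the index-ratio predictions, mirroring the
common practice of confirming marker-index results with a
constrained-regression deconvolution.

## Consensus peaks and the proximity sweep

Two readings of "intersecting peaks from all replicate sets" exist:
region intersection, and anchored filtering that keeps reference-list
peaks supported everywhere. `consensusPeaks()` defaults to the anchored
mode (chained `bedtools intersect -u` semantics, minimum overlap 1 bp)
because published consensus counts are peak counts drawn from a
reference list; region mode is available behind `mode = "region"`. BED
input is 0-based half-open and the convention is honoured everywhere: a
peak `[10, 20)` does not overlap `[20, 30)`, and a TSS at position 25
is 5 bp from that peak (bases strictly between). Distances are
unstranded and gene strand only determines which gene end is the TSS.
In the sweep, ties at the threshold count as "near" (`distance <= t`),
near-set sizes are asserted monotone in the threshold, and a threshold
with an empty side is reported as undefined rather than an error. The
two one-tailed rank-sum tests per threshold ask whether near genes have
lower DE p-values, and lower case-vs-control log2 fold changes, than
far genes.

## Integrated pathway enrichment

Per omics layer, `rankWilcoxEnrich()` ranks all measured features by
p-value (mid-ranks for ties) and runs a one-tailed rank-sum test of
members against the per-pathway complement — a threshold-free
enrichment that is invariant to monotone transforms of the inputs. The
gene layer consumes uncorrected DE p-values: the method ranks raw
evidence and multiplicity is handled once, at the pathway level, by a
BH adjustment over the surviving pathways (whether the original
analysis adjusted at that level is unstated; adjusting is the safer
default and is exposed in the output as a separate column). Layer
p-values are combined by Fisher's method against chi-square(4). The
membership filter is read literally: strictly more than five measured
genes, and at least one measured metabolite. Direction of change is
deliberately not encoded — the test concerns evidence strength, not
sign. One caution established by the closed form: combining helps when
both layers carry comparable evidence (for two equal p-values it
sharpens them up to about p = 0.28) but Fisher's method does not
dominate `min(pA, pB)` in general.

## Metabolomics

Per-metabolite two-group tests default to the two-sided rank-sum test,
for consistency with the rank-based comparisons used elsewhere in the
pipeline (a t-test is available behind a flag); technical replicates
are averaged per subject first to avoid pseudo-replication. Constant
metabolites get p = 1 and a flag. The top-k clustering selects the
union of each comparison's k most significant metabolites (ties broken
lexicographically by id, so selection is reproducible), log-transforms
(+1) and row-z-scores abundances, then Ward-clusters samples; the log
is taken because abundances are log-normal-like and Euclidean
distances on raw abundances would be dominated by the most abundant
metabolites. `ratioCorrelation()` forms a per-sample metabolite ratio,
drops samples with non-positive denominators, and Spearman-correlates
the ratio with the mean normalized expression of a gene pair.

## Numerical and statistical conventions

* Rank-sum tests use the exact null distribution for tie-free samples
  of combined size ≤ 12, otherwise the normal approximation with tie
  and continuity corrections. Spearman p-values likewise use the
  exact/Edgeworth small-sample distribution up to n = 12 without ties,
  and the t approximation beyond.
* Ward clustering is Ward.D2 (squared-Euclidean updates), the modern
  convention; on the fixtures used here the older variant yields the
  same topology.
* PCA fixes component signs by making the largest-magnitude loading
  positive, so results are platform-reproducible.
* The hypergeometric ("Fisher") overlap test reports the upper tail
  P(overlap ≥ k); the chi-square variant uses no continuity correction
  so a table exactly at its expectation scores statistic 0, p = 1.
* All generators and resampling functions take explicit integer seeds
  and restore the caller's RNG state (`withr::with_seed`); a repeated
  CLI `simulate` run is byte-identical.
* Problem sizes in the shipped checks (2,000-gene cohorts at 24 + 24
  for calibration, 600-gene cohorts at 10 + 10 across 100 seeds for the
  sweep, 1,000 null sets where 10,000 are quoted for the original
  analyses) were chosen as the package's own desk-scale defaults; all
  are configurable upward.

## Known limitations

The NB-LRT stand-in approximates, but does not numerically replicate, a
shrinkage-based DESeq2 analysis; its p-values agree in distribution and
calibration, not gene-by-gene. The consensus-peak count printed for the
three public EGR1 ChIP-seq replicates (4,121) can be reproduced with
`inst/scripts/fetch_encode_peaks.R`, which needs network access and is
therefore not part of the test suite. The index-ratio deconvolution is
only as good as marker exclusivity; with weakly specific markers its
predictions acquire the `(1 - w) / f` bias described above, which is a
property of the method, not of the implementation.
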