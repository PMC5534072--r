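# Synthetic cohort generator with planted ground truth. Every downstream
# stage (indices, DE, proximity sweep, pathway integration, metabolite
# coupling) is benchmarked against the truth ledger this module records.

#' Build reference expression profiles for a panel of brain cell types
#'
#' Baseline per-gene means are log-normal; each cell type receives a
#' disjoint random marker set whose mean in its own type is boosted to
#' `specificityFold` times the maximum mean across the other types, so
#' the panel satisfies the marker specificity constraint by construction.
#'
#' @param nGenes number of genes (>= 100).
#' @param cellTypes character vector of at least two cell type names.
#' @param markerFrac fraction of genes assigned as markers to each type;
#'   `markerFrac * nGenes` must be at least 10.
#' @param specificityFold fold-change defining marker specificity
#'   (default 50, i.e. near-exclusive markers).
#' @param seed integer seed.
#' @return a [CellProfilePanel].
#' @export
makeProfiles <- function(nGenes = 2000L,
                         cellTypes = c("neuron", "astrocyte",
                                       "oligodendrocyte", "microglia"),
                         markerFrac = 0.02, specificityFold = 50,
                         seed = NULL) {
  if (nGenes < 100L) fail("nGenes must be at least 100")
  if (length(cellTypes) < 2L) fail("at least two cell types required")
  nMark <- round(markerFrac * nGenes)
  if (nMark < 10L) fail("markerFrac * nGenes must be at least 10 per type")
  if (nMark * length(cellTypes) > nGenes)
    fail("marker sets would overlap: too many markers for nGenes")
  withSeed(seed, {
    genes <- sprintf("g%05d", seq_len(nGenes))
    base <- stats::rlnorm(nGenes, meanlog = log(50), sdlog = 1)
    m <- vapply(cellTypes, function(ct)
      base * stats::rlnorm(nGenes, meanlog = 0, sdlog = 0.15),
      numeric(nGenes))
    dimnames(m) <- list(genes, cellTypes)
    idx <- sample.int(nGenes, nMark * length(cellTypes))
    markers <- split(genes[idx],
                     rep(cellTypes, each = nMark))[cellTypes]
    for (ct in cellTypes) {
      g <- markers[[ct]]
      others <- setdiff(cellTypes, ct)
      m[g, ct] <- specificityFold *
        apply(m[g, others, drop = FALSE], 1L, max)
    }
    new("CellProfilePanel", meanExpression = m, markers = markers,
        specificityFold = specificityFold)
  })
}

#' Draw a purified cell-type count vector
#'
#' Negative-binomial counts (variance `mu + dispersion * mu^2`) with
#' per-gene means proportional to the panel profile, scaled so the
#' expected total is `totalReads`. `dispersion = 0` degenerates to
#' Poisson; `totalReads = 0` returns the zero vector.
#'
#' @param panel a [CellProfilePanel].
#' @param cellType one of the panel's cell types.
#' @param totalReads expected library size.
#' @param dispersion NB dispersion alpha (>= 0).
#' @param seed integer seed.
#' @return named integer count vector over the panel's genes.
#' @export
samplePureCounts <- function(panel, cellType, totalReads,
                             dispersion = 0.05, seed = NULL) {
  stopifnot(is(panel, "CellProfilePanel"))
  if (!cellType %in% cellTypes(panel))
    fail("unknown cell type: ", cellType)
  assertScalarNumber(totalReads, "totalReads", lower = 0)
  assertScalarNumber(dispersion, "dispersion", lower = 0)
  prof <- meanExpression(panel)[, cellType]
  mu <- prof / sum(prof) * totalReads
  withSeed(seed, {
    cnt <- if (totalReads == 0) integer(length(mu))
      else if (dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    names(cnt) <- names(mu)
    cnt
  })
}

#' Synthetic genome annotation with planted consensus peaks
#'
#' Places gene TSSs uniformly on one synthetic chromosome and builds
#' `nPeakSets` replicate peak sets: every set contains jittered copies of
#' a common core peak list (the planted consensus) plus its own private
#' peaks. The truth ledger records each gene's distance to the nearest
#' core peak.
#'
#' @param nGenes number of TSSs.
#' @param nPeaks number of core (consensus) peaks.
#' @param peakWidth width of every peak in bp (> 0).
#' @param nPeakSets number of replicate sets (>= 2).
#' @param jitter maximal boundary noise in bp applied to core peaks in
#'   each replicate set.
#' @param nPrivatePeaks private peaks added per set.
#' @param chromLength synthetic chromosome length (default 10 Mb).
#' @param seed integer seed.
#' @return list with `tss` (a [readTss()]-style data.frame), `peakSets`
#'   (list of `GRanges`), `corePeaks` (`GRanges`) and `truth` (data.frame
#'   `gene_id`, `distance` to the nearest core peak in bp).
#' @export
makeGenome <- function(nGenes = 2000L, nPeaks = 150L, peakWidth = 400L,
                       nPeakSets = 3L, jitter = 20L, nPrivatePeaks = 50L,
                       chromLength = 1e7, seed = NULL) {
  if (peakWidth <= 0) fail("peakWidth must be positive")
  if (nPeakSets < 2L) fail("at least two peak sets required")
  withSeed(seed, {
    tssPos <- sort(sample.int(chromLength - 1L, nGenes))
    tss <- data.frame(gene_id = sprintf("g%05d", seq_len(nGenes)),
                      chrom = "chrS", tss = tssPos,
                      strand = sample(c("+", "-"), nGenes, replace = TRUE),
                      stringsAsFactors = FALSE)
    coreStart <- sort(sample.int(chromLength - peakWidth - 2L * jitter - 1L,
                                 nPeaks)) + jitter
    core <- GRanges("chrS", IRanges(coreStart + 1L,
                                    coreStart + peakWidth))
    peakSets <- lapply(seq_len(nPeakSets), function(i) {
      js <- if (jitter > 0)
        sample(seq.int(-jitter, jitter), nPeaks, replace = TRUE)
        else integer(nPeaks)
      je <- if (jitter > 0)
        sample(seq.int(-jitter, jitter), nPeaks, replace = TRUE)
        else integer(nPeaks)
      s0 <- pmax(coreStart + js, 0L)
      e0 <- pmax(coreStart + peakWidth + je, s0 + 1L)
      gr <- GRanges("chrS", IRanges(s0 + 1L, e0))
      if (nPrivatePeaks > 0L) {
        ps <- sample.int(chromLength - peakWidth - 1L, nPrivatePeaks)
        gr <- c(gr, GRanges("chrS", IRanges(ps + 1L, ps + peakWidth)))
      }
      sort(gr)
    })
    # brute-force truth distance to the nearest core peak (0-based bp gap)
    s0 <- coreStart; e0 <- coreStart + peakWidth
    dist <- vapply(tssPos, function(t0) {
      d <- ifelse(t0 >= s0 & t0 < e0, 0,
                  ifelse(t0 < s0, s0 - t0 - 1, t0 - e0))
      min(d)
    }, numeric(1L))
    list(tss = tss, peakSets = peakSets, corePeaks = core,
         truth = data.frame(gene_id = tss$gene_id, distance = dist,
                            stringsAsFactors = FALSE))
  })
}

#' Default synthetic cohort configuration
#'
#' The returned list holds the study conditions emulated by
#' [makeCohort()]: four diagnosis groups of 24 AnCg samples, cell-type
#' mixing weights drawn per sample (neuron weight Beta-distributed with
#' mean 0.45 in controls, shifted down in SZ and BPD), negative-binomial
#' counts with a shared dispersion, planted per-disorder log2 effects on
#' randomly chosen genes, an optional transcription-factor effect on
#' genes whose TSS lies near a planted consensus peak, and a per-sample
#' PRUA covariate that thins observed counts.
#'
#' @param ... named overrides of any default.
#' @return configuration list consumed by [makeCohort()].
#' @export
cohortConfig <- function(...) {
  cfg <- list(
    groupSizes = c(CTL = 24L, SZ = 24L, BPD = 24L, MDD = 24L),
    region = "AnCg",
    nGenes = 2000L,
    cellTypes = c("neuron", "astrocyte", "oligodendrocyte", "microglia"),
    markerFrac = 0.02,
    specificityFold = 50,
    totalReads = 2e5,
    dispersion = 0.05,
    baseWeights = c(neuron = 0.45, astrocyte = 0.30,
                    oligodendrocyte = 0.15, microglia = 0.10),
    neuronShift = c(CTL = 0, SZ = -0.10, BPD = -0.08, MDD = 0),
    weightConcentration = 60,
    nDEGenes = c(CTL = 0L, SZ = 50L, BPD = 50L, MDD = 10L),
    deLog2FC = 1,
    tfEffect = 0,          # log2; set negative to plant peak-proximal loss
    tfWindow = 1000,
    tfDisorders = "SZ",
    genome = NULL,         # makeGenome() output enabling the TF effect
    pruaMean = 0.85,
    pruaConcentration = 40,
    pruaCaseShift = 0      # confounding: added to case-group PRUA mean
  )
  override <- list(...)
  for (nm in names(override)) cfg[[nm]] <- override[[nm]]
  cfg
}

#' Generate a synthetic case/control cohort with planted truth
#'
#' Per-sample counts arise from a mixture of the panel's cell-type
#' profiles (weights recorded in the truth ledger), scaled to the target
#' library size, modulated by planted disorder effects and the optional
#' peak-proximity effect, drawn negative-binomially, and finally thinned
#' binomially with per-sample retention proportional to PRUA — the
#' alignment-quality distortion the normalization stage residualizes out.
#'
#' @param config list from [cohortConfig()].
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix), `samples`
#'   (sample metadata data.frame), `panel` (the [CellProfilePanel]) and
#'   `truth` (mixing weights, per-disorder planted log2 effects, TF
#'   target genes, PRUA retention).
#' @export
makeCohort <- function(config = cohortConfig(), seed = NULL) {
  gs <- config$groupSizes
  if (any(gs[gs > 0] < 3L)) fail("group sizes below 3 are not supported")
  withSeed(seed, {
    panel <- makeProfiles(config$nGenes, config$cellTypes,
                          config$markerFrac, config$specificityFold)
    genes <- rownames(meanExpression(panel))
    profiles <- apply(meanExpression(panel), 2L, function(p) p / sum(p))
    diag <- rep(names(gs), gs)
    n <- length(diag)
    ids <- sprintf("S%03d", seq_len(n))

    bw <- config$baseWeights[config$cellTypes]
    bw <- bw / sum(bw)
    conc <- config$weightConcentration
    wNeuronMean <- pmin(pmax(bw["neuron"] +
                               config$neuronShift[diag], 0.02), 0.98)
    wNeuron <- stats::rbeta(n, wNeuronMean * conc,
                            (1 - wNeuronMean) * conc)
    others <- setdiff(config$cellTypes, "neuron")
    weights <- matrix(0, n, length(config$cellTypes),
                      dimnames = list(ids, config$cellTypes))
    weights[, "neuron"] <- wNeuron
    weights[, others] <- (1 - wNeuron) %o% (bw[others] / sum(bw[others]))

    # planted per-disorder effects on randomly chosen non-marker genes
    markerGenes <- unlist(markerSets(panel), use.names = FALSE)
    free <- setdiff(genes, markerGenes)
    effects <- list()
    for (dg in names(gs)) {
      k <- if (dg %in% names(config$nDEGenes))
        config$nDEGenes[[dg]] else 0L
      if (k == 0L) next
      pick <- sample(free, k)
      effects[[dg]] <- stats::setNames(
        sample(c(-1, 1), k, replace = TRUE) * config$deLog2FC, pick)
    }

    tfTargets <- character()
    if (!is.null(config$genome) && config$tfEffect != 0) {
      tr <- config$genome$truth
      tfTargets <- intersect(tr$gene_id[tr$distance <= config$tfWindow],
                             genes)
    }

    pruaMean <- pmin(pmax(config$pruaMean +
                            ifelse(diag == "CTL", 0, config$pruaCaseShift),
                          0.05), 0.99)
    prua <- stats::rbeta(n, pruaMean * config$pruaConcentration,
                         (1 - pruaMean) * config$pruaConcentration)
    retention <- prua / max(prua)

    counts <- matrix(0L, length(genes), n, dimnames = list(genes, ids))
    for (i in seq_len(n)) {
      mu <- as.vector(profiles %*% weights[i, ]) * config$totalReads
      eff <- effects[[diag[i]]]
      if (!is.null(eff)) {
        mu[match(names(eff), genes)] <-
          mu[match(names(eff), genes)] * 2^eff
      }
      if (length(tfTargets) && diag[i] %in% config$tfDisorders) {
        j <- match(tfTargets, genes)
        mu[j] <- mu[j] * 2^config$tfEffect
      }
      raw <- if (config$dispersion == 0) stats::rpois(length(mu), mu)
        else stats::rnbinom(length(mu), mu = mu,
                            size = 1 / config$dispersion)
      counts[, i] <- stats::rbinom(length(raw), raw, retention[i])
    }

    samples <- data.frame(
      sample_id = ids, diagnosis = diag, region = config$region,
      age = round(stats::rnorm(n, 50, 10), 1),
      pH = round(stats::rnorm(n, 6.8, 0.15), 2),
      PMI = round(pmax(stats::rnorm(n, 20, 5), 1), 1),
      PRUA = round(prua, 4), stringsAsFactors = FALSE)

    truth <- list(weights = weights, disorderEffects = effects,
                  tfTargets = tfTargets, tfEffect = config$tfEffect,
                  retention = stats::setNames(retention, ids))
    list(counts = counts, samples = samples, panel = panel, truth = truth)
  })
}

#' Generate metabolite abundances coupled to gene expression
#'
#' Coupled metabolites follow, on the log scale, a linear combination of
#' the standardized mean normalized expression of their source genes and
#' independent Gaussian noise, weighted so the log-scale correlation with
#' the gene signal approaches the coupling `rho` at `noiseSd = 1` and
#' tends to 1 as `noiseSd` tends to 0. Uncoupled metabolites are
#' independent log-normal.
#'
#' @param norm a [NormalizedExpression] (or genes x samples matrix) for
#'   the cohort's samples.
#' @param nMetabolites total number of metabolites (default 141).
#' @param couplings list of `list(metabolite =, genes =, rho =)` entries
#'   with `rho` in (0, 1].
#' @param noiseSd multiplier on the calibrated noise term (default 1).
#' @param seed integer seed.
#' @return non-negative metabolite x sample abundance matrix.
#' @export
generateMetabolites <- function(norm, nMetabolites = 141L,
                                couplings = list(), noiseSd = 1,
                                seed = NULL) {
  v <- if (is(norm, "NormalizedExpression")) exprValues(norm) else norm
  nSamp <- ncol(v)
  coupledNames <- vapply(couplings, `[[`, character(1L), "metabolite")
  if (anyDuplicated(coupledNames)) fail("duplicate coupled metabolite name")
  for (cp in couplings) {
    if (!is.numeric(cp$rho) || cp$rho <= 0 || cp$rho > 1)
      fail("coupling rho must lie in (0, 1]")
    if (!all(cp$genes %in% rownames(v)))
      fail("coupling source genes missing from expression matrix")
  }
  nFree <- nMetabolites - length(couplings)
  if (nFree < 0) fail("more couplings than metabolites")
  withSeed(seed, {
    out <- matrix(0, nMetabolites, nSamp)
    ids <- character(nMetabolites)
    row <- 1L
    for (cp in couplings) {
      z <- colMeans(v[cp$genes, , drop = FALSE])
      zs <- stats::sd(z)
      z <- if (zs > 0) (z - mean(z)) / zs else z * 0
      w <- cp$rho * z +
        noiseSd * sqrt(1 - cp$rho^2) * stats::rnorm(nSamp)
      out[row, ] <- exp(5 + 0.6 * w)
      ids[row] <- cp$metabolite
      row <- row + 1L
    }
    if (nFree > 0) {
      free <- matrix(stats::rlnorm(nFree * nSamp, meanlog = 5,
                                   sdlog = 0.6), nFree, nSamp)
      out[row:nMetabolites, ] <- free
      ids[row:nMetabolites] <- sprintf("M%03d", seq_len(nFree))
    }
    dimnames(out) <- list(ids, colnames(v))
    out
  })
}
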