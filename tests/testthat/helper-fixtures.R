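# Shared small fixtures, built once per test run.

fixtureEnv <- new.env()

# 400-gene, 8+8 CTL/SZ cohort with 20 planted effects, plus its DE table
smallCohortDE <- function() {
  if (is.null(fixtureEnv$small)) {
    cfg <- cohortConfig(groupSizes = c(CTL = 8L, SZ = 8L, BPD = 0L,
                                       MDD = 0L),
                        nGenes = 400L, markerFrac = 0.05,
                        nDEGenes = c(SZ = 20L), totalReads = 5e4)
    co <- makeCohort(cfg, seed = 101L)
    de <- filterAndAdjust(nbLRT(co$counts, co$samples, c("SZ", "CTL")))
    fixtureEnv$small <- list(cohort = co, de = de)
  }
  fixtureEnv$small
}

# deterministic DETable with controllable columns
madeDETable <- function(n = 100L, seed = 1L) {
  withr::with_seed(seed, {
    DETable(gene_id = sprintf("g%04d", seq_len(n)),
            baseMean = stats::rlnorm(n, log(50), 0.5),
            log2FC = stats::rnorm(n, 0, 0.5),
            dispersion = rep(0.05, n),
            pvalue = stats::runif(n))
  })
}
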