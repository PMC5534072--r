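test_that("method-of-moments dispersion recovers the simulation truth", {
  withr::with_seed(31, {
    grp <- factor(rep(c("a", "b"), each = 24))
    # Poisson genes: alpha estimates concentrate near zero
    pois <- matrix(rpois(300 * 48, 100), 300)
    dimnames(pois) <- list(paste0("g", 1:300), paste0("s", 1:48))
    aP <- estimateDispersionsMoM(pois, grp, rep(1, 48), shrink = 0)
    expect_gt(mean(aP <= 0.05), 0.9)
    # NB genes at alpha = 0.2
    nb <- matrix(rnbinom(300 * 48, mu = 100, size = 5), 300)
    dimnames(nb) <- dimnames(pois)
    aN <- estimateDispersionsMoM(nb, grp, rep(1, 48), shrink = 0)
    expect_lt(abs(mean(aN) - 0.2), 0.05)
    # a constant gene has zero excess variance
    const <- pois; const[1, ] <- 50L
    aC <- estimateDispersionsMoM(const, grp, rep(1, 48), shrink = 0)
    expect_equal(unname(aC[1]), 0)
    # all-zero genes are flagged undefined
    zero <- pois; zero[2, ] <- 0L
    expect_true(is.na(estimateDispersionsMoM(zero, grp, rep(1, 48))[2]))
  })
})

test_that("at zero dispersion the LRT equals the Poisson deviance difference", {
  sc <- smallCohortDE()
  co <- sc$cohort
  counts <- co$counts[1:10, ]
  sf <- computeSizeFactors(co$counts)
  de <- nbLRT(counts, co$samples, c("SZ", "CTL"), sizeFactors = sf,
              dispersions = rep(0, 10))
  # independent oracle: stats::glm Poisson fits with anova deviance
  dat <- co$samples
  dat$disorder <- factor(dat$diagnosis, levels = c("CTL", "SZ"))
  for (g in 1:10) {
    dat$y <- counts[g, dat$sample_id]
    full <- stats::glm(y ~ age + pH + PMI + PRUA + disorder, data = dat,
                       family = poisson(), offset = log(sf))
    red <- stats::glm(y ~ age + pH + PMI + PRUA, data = dat,
                      family = poisson(), offset = log(sf))
    lrt <- red$deviance - full$deviance
    expect_equal(de$pvalue[g],
                 pchisq(max(lrt, 0), 1, lower.tail = FALSE),
                 tolerance = 1e-6)
    expect_equal(de$log2FC[g], coef(full)[["disorderSZ"]] / log(2),
                 tolerance = 1e-6)
  }
})

test_that("the LRT is invariant to sample order and flips sign with the contrast", {
  sc <- smallCohortDE()
  co <- sc$cohort
  counts <- co$counts[1:40, ]
  de1 <- nbLRT(counts, co$samples, c("SZ", "CTL"))
  perm <- sample(nrow(co$samples))
  de2 <- nbLRT(counts[, co$samples$sample_id[perm]],
               co$samples[perm, ], c("SZ", "CTL"))
  expect_equal(de1$pvalue, de2$pvalue, tolerance = 1e-6)
  flip <- nbLRT(counts, co$samples, c("CTL", "SZ"))
  expect_equal(flip$log2FC, -de1$log2FC, tolerance = 1e-6)
  expect_equal(flip$pvalue, de1$pvalue, tolerance = 1e-6)
})

test_that("a collinear design is rejected with the offending column named", {
  sc <- smallCohortDE()
  co <- sc$cohort
  samp <- co$samples
  samp$dup <- samp$age  # exact copy
  expect_error(nbLRT(co$counts[1:5, ], samp, c("SZ", "CTL"),
                     covariates = c("age", "dup")),
               "collinear")
})

test_that("independent filtering excludes low-expression genes from the FDR", {
  de <- DETable(gene_id = paste0("g", 1:5),
                baseMean = c(5, 12, 12, 12, 12),
                log2FC = 0, dispersion = 0.1,
                pvalue = c(0.001, 0.01, 0.02, 0.03, 0.04))
  adj <- filterAndAdjust(de, minBaseMean = 10)
  expect_true(is.na(adj$padj[1]))
  expect_equal(sum(!is.na(adj$padj)), 4L)
  expect_equal(adj$padj[2:5], bhAdjust(c(0.01, 0.02, 0.03, 0.04)))
  all4 <- filterAndAdjust(de, minBaseMean = 0)
  expect_equal(sum(!is.na(all4$padj)), 5L)
})

test_that("cross-disorder concordance detects identity and planted sharing", {
  de <- madeDETable(500)
  self <- crossdisorderConcordance(de, de)
  expect_equal(self$rho, 1)
  expect_equal(self$nBoth, self$nA)
  withr::with_seed(17, {
    # planted shared axis: both tables significant on the same 50 genes
    lfcShared <- rnorm(500, 0, 0.2)
    hot <- sample(500, 50)
    lfcShared[hot] <- rnorm(50, 2, 0.2)
    pA <- runif(500); pA[hot] <- runif(50, 0, 1e-4)
    pB <- runif(500); pB[hot] <- runif(50, 0, 1e-4)
    mk <- function(p, lfc) DETable(gene_id = paste0("g", 1:500),
                                   baseMean = 50, log2FC = lfc,
                                   dispersion = 0.05, pvalue = p)
    cc <- crossdisorderConcordance(mk(pA, lfcShared), mk(pB, lfcShared))
    expect_lt(cc$overlap$p.value, 1e-6)
    expect_gt(cc$rho, 0.2)
  })
  other <- DETable(gene_id = paste0("x", 1:10), baseMean = 50,
                   log2FC = 0, dispersion = 0.05, pvalue = 0.5)
  expect_error(crossdisorderConcordance(de, other), "shared")
})

test_that("modelling PRUA suppresses confounding-driven false positives", {
  worse <- 0L
  for (s in 1:5) {
    cfg <- cohortConfig(groupSizes = c(CTL = 12L, SZ = 12L, BPD = 0L,
                                       MDD = 0L),
                        nGenes = 400L, markerFrac = 0.05,
                        nDEGenes = c(SZ = 0L), pruaCaseShift = -0.12,
                        totalReads = 1e5)
    co <- makeCohort(cfg, seed = 300 + s)
    withPrua <- nbLRT(co$counts, co$samples, c("SZ", "CTL"))
    woPrua <- nbLRT(co$counts, co$samples, c("SZ", "CTL"),
                    covariates = c("age", "pH", "PMI"))
    if (sum(withPrua$pvalue < 0.05, na.rm = TRUE) <
          sum(woPrua$pvalue < 0.05, na.rm = TRUE)) worse <- worse + 1L
  }
  expect_gte(worse, 4L)
})
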