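test_that("indices are marker medians and ignore non-marker genes", {
  v <- matrix(c(1, 5, 9, 2), 4, 1,
              dimnames = list(c("g1", "g2", "g3", "g4"), "s"))
  idx <- computeIndex(v, list(neuron = c("g1", "g2", "g3")))
  expect_equal(idx["s", "neuron"], 5)
  # adding a non-marker gene changes nothing
  v2 <- rbind(v, g5 = 100)
  expect_equal(computeIndex(v2, list(neuron = c("g1", "g2", "g3"))), idx)
  # constant matrix: every index equals the constant
  vc <- matrix(3, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_true(all(computeIndex(vc, list(t1 = c("g1", "g2"),
                                        t2 = "g3")) == 3))
  expect_warning(computeIndex(v, list(neuron = c("g1", "gZ"))), "dropped")
  expect_error(suppressWarnings(computeIndex(v, list(glia = "gZ"))),
               "glia")
})

test_that("down-sampling is an exact-total draw without replacement", {
  x <- c(a = 10L, b = 0L, c = 25L, d = 5L)
  expect_identical(downsampleCounts(x, sum(x)), x)
  expect_error(downsampleCounts(x, 100), "exceeds")
  d <- downsampleCounts(x, 13, seed = 4)
  expect_equal(sum(d), 13)
  expect_true(all(d <= x))
  expect_equal(d[["b"]], 0L)
  # hypergeometric moments: per-gene mean = count * target / total
  withr::with_seed(12, {
    reps <- replicate(400, downsampleCounts(x, 20))
    expMean <- x * 20 / sum(x)
    n <- sum(x); K <- 20
    vr <- x * (K / n) * (1 - x / n) * ((n - K) / (n - 1))
    se <- sqrt(vr / 400)
    expect_true(all(abs(rowMeans(reps) - expMean) <=
                      3 * pmax(se, 1e-9) + 1e-9))
  })
})

test_that("in-silico mixing hits the exact component read targets", {
  withr::with_seed(14, {
    neu <- rpois(50, 200); ast <- rpois(50, 200)
    names(neu) <- names(ast) <- paste0("g", 1:50)
    mx <- mixInSilico(list(neuron = neu, astrocyte = ast), c(0.8, 0.2),
                      commonTotal = 5000, seed = 1)
    expect_equal(unname(mx$targets), c(4000, 1000))
    expect_equal(sum(mx$counts), 5000)
    only <- mixInSilico(list(neuron = neu, astrocyte = ast), c(1, 0),
                        commonTotal = 3000, seed = 2)
    expect_true(all(only$counts <= neu))
    expect_equal(sum(only$counts), 3000)
    bad <- ast; names(bad) <- rev(names(ast))
    expect_error(mixInSilico(list(neu, bad), c(0.5, 0.5)), "gene order")
  })
})

test_that("proportion prediction is the index ratio, exact on noiseless input", {
  expect_equal(predictProportion(40, 50)$estimate, 0.8)
  expect_equal(predictProportion(50, 50)$estimate, 1)
  expect_error(predictProportion(10, 0), "positive")
  # exactness property: observed = w * purified recovers w for all w
  w <- seq(0, 1, by = 0.1)
  expect_equal(predictProportion(w * 42, 42)$estimate, w)
  expect_equal(predictProportion(c(-0.2, 1.4), 1)$clamped, c(0, 1))
})

test_that("marker indices outperform size-matched null sets on planted mixtures", {
  panel <- makeProfiles(nGenes = 600, markerFrac = 0.04, seed = 23)
  neu <- samplePureCounts(panel, "neuron", 4e5, seed = 1)
  ast <- samplePureCounts(panel, "astrocyte", 4e5, seed = 2)
  ws <- c(0.2, 0.5, 0.8)
  ct <- min(sum(neu), sum(ast))
  mixes <- vapply(seq_along(ws), function(i)
    mixInSilico(list(neu, ast), c(ws[i], 1 - ws[i]), commonTotal = ct,
                seed = 10 + i)$counts, numeric(length(neu)))
  dimnames(mixes) <- list(names(neu), paste0("m", ws))
  cpm <- sweep(cbind(pure = neu * (ct / sum(neu)), mixes), 2,
               c(ct, colSums(mixes)) / 1e6, "/")
  res <- nullIndexMSE(cpm[, -1], cpm[, 1], ws,
                      markerSets(panel)$neuron, nNull = 200, seed = 3)
  expect_lt(res$p.value, 0.05)
  expect_lt(res$observedMSE, 0.05^2 * 3)
  expect_error(nullIndexMSE(cpm[, -1], cpm[, 1], ws,
                            markerSets(panel)$neuron, nNull = 10), "100")
})

test_that("expression-matched nulls respect the tolerance and detect planted shifts", {
  withr::with_seed(33, {
    n <- 600
    de <- DETable(gene_id = sprintf("g%04d", 1:n),
                  baseMean = rlnorm(n, log(100), 0.3),
                  log2FC = rnorm(n, 0, 0.3),
                  dispersion = 0.05, pvalue = runif(n))
    set <- sample(de$gene_id[de$baseMean > 50 & de$baseMean < 200], 25)
    # planted downward shift on the set
    df <- as(de, "DFrame")
    df$log2FC[match(set, de$gene_id)] <-
      df$log2FC[match(set, de$gene_id)] - 0.8
    de <- new("DETable", df)
    res <- matchedNullFoldChange(de, set, nNull = 400,
                                 returnNullSets = TRUE, seed = 7)
    expect_lte(res$p.value, 0.01)
    # every sampled null gene is matched within 5% on baseMean
    bm <- de$baseMean
    target <- bm[match(set, de$gene_id)]
    for (s in res$nullSets[1:20]) {
      expect_true(all(abs(bm[s] - target) <= 0.05 * target + 1e-9))
    }
    # a null draw of the statistic is itself unremarkable
    nullSet <- sample(setdiff(de$gene_id[de$baseMean > 50 &
                                           de$baseMean < 200], set), 25)
    resNull <- matchedNullFoldChange(de, nullSet, nNull = 400, seed = 8)
    expect_gt(resNull$p.value, 0.05)
  })
})

test_that("fold changes correlate negatively with planted neuron specificity", {
  panel <- makeProfiles(nGenes = 400, markerFrac = 0.05, seed = 41)
  spec <- log2(meanExpression(panel)[, "neuron"] /
                 rowMeans(meanExpression(panel)[, -1]))
  de <- DETable(gene_id = rownames(meanExpression(panel)),
                baseMean = 100, log2FC = -spec, dispersion = 0.05,
                pvalue = 0.5)
  res <- specificityCorrelation(de, panel, "neuron")
  expect_equal(res$rho, -1, tolerance = 1e-12)
  expect_error(specificityCorrelation(de, panel, "ependymal"), "unknown")
})

test_that("constrained least squares recovers exact and pure mixtures", {
  withr::with_seed(19, {
    S <- matrix(rexp(80 * 3, 1 / 50), 80, 3,
                dimnames = list(paste0("g", 1:80),
                                c("neuron", "astrocyte", "microglia")))
    w0 <- c(0.6, 0.4, 0)
    x <- as.vector(S %*% w0)
    names(x) <- rownames(S)
    expect_equal(unname(lsDeconvolve(x, S)[1, ]), w0, tolerance = 1e-6)
    pure <- S[, 2]
    names(pure) <- rownames(S)
    expect_equal(unname(lsDeconvolve(pure, S)[1, 2]), 1,
                 tolerance = 1e-6)
    bad <- S; bad[, 3] <- 2 * bad[, 1]
    expect_error(lsDeconvolve(x, bad), "rank")
    # noisy mixtures: LS weights track the index-ratio predictions
    ws <- seq(0.15, 0.85, length.out = 8)
    mixes <- vapply(ws, function(w)
      rpois(80, S %*% c(w, 1 - w, 0)), numeric(80))
    rownames(mixes) <- rownames(S)
    wHat <- lsDeconvolve(mixes, S)[, 1]
    expect_gt(cor(wHat, ws, method = "spearman"), 0.8)
  })
})
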