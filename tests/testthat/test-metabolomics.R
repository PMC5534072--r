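mkSamples <- function(n1, n2, labels = c("SZ", "CTL")) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n1 + n2)),
             diagnosis = rep(labels, c(n1, n2)),
             region = "AnCg", age = 50, pH = 6.8, PMI = 20, PRUA = 0.8)
}

test_that("metabolite tests are symmetric, rank-based and flag constants", {
  withr::with_seed(61, {
    samp <- mkSamples(6, 6)
    m <- matrix(rlnorm(8 * 12, 5, 0.5), 8, 12,
                dimnames = list(sprintf("m%02d", 1:8), samp$sample_id))
    m[3, ] <- 7  # constant metabolite
    res <- metabDiff(m, samp, c("SZ", "CTL"))
    expect_equal(res$p[3], 1)
    expect_true(res$flagged[3])
    expect_true(all(res$fdr >= res$p - 1e-12))
    # label swap leaves two-sided p unchanged
    res2 <- metabDiff(m, samp, c("CTL", "SZ"))
    expect_equal(res2$p, res$p)
    # monotone rescaling of a metabolite leaves its p unchanged
    m2 <- m; m2[1, ] <- exp(m2[1, ] / 2)
    expect_equal(metabDiff(m2, samp, c("SZ", "CTL"))$p[1], res$p[1])
  })
})

test_that("technical replicates are averaged per subject before testing", {
  withr::with_seed(63, {
    samp <- mkSamples(6, 6)
    subj <- stats::setNames(rep(sprintf("P%02d", 1:6), each = 2),
                            samp$sample_id)
    m <- matrix(rlnorm(2 * 12, 5, 0.4), 2, 12,
                dimnames = list(c("m01", "m02"), samp$sample_id))
    res <- metabDiff(m, samp, c("SZ", "CTL"), subject = subj)
    # oracle: rank-sum on the 3+3 subject means
    means <- t(apply(m, 1L, function(x) tapply(x, subj, mean)))
    want <- apply(means, 1L, function(x)
      stats::wilcox.test(x[1:3], x[4:6], exact = TRUE)$p.value)
    expect_equal(res$p, unname(want))
    # too few subjects per group is rejected
    subjBad <- stats::setNames(rep(c("P1", "P2", "P3", "P4"), each = 3),
                               samp$sample_id)
    expect_error(metabDiff(m, samp, c("SZ", "CTL"), subject = subjBad),
                 "3 samples")
  })
})

test_that("top-k selection unions comparisons with a lexicographic tie-break", {
  withr::with_seed(65, {
    ids <- sprintf("m%02d", 1:40)
    mkRes <- function(top) {
      p <- stats::setNames(runif(40, 0.5, 1), ids)
      p[top] <- runif(length(top), 0, 1e-4)
      data.frame(metabolite = ids, p = unname(p))
    }
    resA <- mkRes(ids[1:10]); resB <- mkRes(ids[11:20])
    resC <- mkRes(ids[21:30])
    samp <- mkSamples(10, 10)
    m <- matrix(rlnorm(40 * 20, 5, 0.5), 40, 20,
                dimnames = list(ids, samp$sample_id))
    sel <- topKClustering(m, list(resA, resB, resC), k = 10)
    expect_length(sel$selected, 30L)  # disjoint tops: union of 3 x 10
    # overlapping tops shrink the union without duplicating
    sel2 <- topKClustering(m, list(resA, resA, resC), k = 10)
    expect_length(sel2$selected, 20L)
    expect_equal(anyDuplicated(sel2$selected), 0L)
    # ties broken by metabolite id
    tie <- data.frame(metabolite = ids, p = rep(0.5, 40))
    sel3 <- topKClustering(m, list(tie, tie), k = 3)
    expect_identical(sort(sel3$selected), sort(ids[1:3]))
  })
})

test_that("clustering on planted metabolite structure recovers the groups", {
  withr::with_seed(67, {
    samp <- mkSamples(12, 12)
    ids <- sprintf("m%02d", 1:20)
    logm <- matrix(rnorm(20 * 24, 5, 0.3), 20, 24)
    logm[1:10, 1:12] <- logm[1:10, 1:12] + 1.5  # shifted in SZ samples
    m <- exp(logm)
    dimnames(m) <- list(ids, samp$sample_id)
    res <- metabDiff(m, samp, c("SZ", "CTL"))
    cl <- topKClustering(m, list(res, res), k = 10)
    agree <- max(mean((cl$labels == 1) == (samp$diagnosis == "SZ")),
                 mean((cl$labels == 2) == (samp$diagnosis == "SZ")))
    expect_gt(agree, 0.9)
  })
})

test_that("ratio correlations recover planted gene-metabolite couplings", {
  withr::with_seed(69, {
    v <- matrix(rnorm(40 * 4, 8, 1), 4, 40,
                dimnames = list(c("GAD1", "GAD2", "gX", "gY"),
                                sprintf("S%03d", 1:40)))
    metab <- generateMetabolites(v, nMetabolites = 3,
      couplings = list(list(metabolite = "GABA",
                            genes = c("GAD1", "GAD2"), rho = 0.9)),
      seed = 5)
    # a near-constant denominator keeps the planted ratio signal intact
    metab <- rbind(metab, glutamate = exp(5 + rnorm(40, 0, 0.05)))
    res <- ratioCorrelation(metab, "GABA", "glutamate", v,
                            c("GAD1", "GAD2"))
    expect_gt(res$rho, 0.6)
    expect_lt(res$p.value, 0.01)
    # uncoupled metabolite: no signal
    res0 <- ratioCorrelation(metab, "M001", "glutamate", v,
                             c("GAD1", "GAD2"))
    expect_lt(abs(res0$rho), 0.4)
    # constant predictor is flagged undefined
    vc <- v; vc["GAD1", ] <- 1; vc["GAD2", ] <- 1
    resC <- ratioCorrelation(metab, "GABA", "glutamate", vc,
                             c("GAD1", "GAD2"))
    expect_false(resC$defined)
    expect_error(ratioCorrelation(metab, "nope", "glutamate", v, "GAD1"),
                 "not measured")
  })
})
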