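mkExpr <- function(values, samples = "s1") {
  matrix(rep(values, length(samples)), length(values), length(samples),
         dimnames = list(names(values), samples))
}

test_that("fraction-of-pure reproduces identity and hand mean/SEM, and is scale-equivariant", {
  ms <- toyMarkerSet(c("g1", "g2"), c("astrocyte", "astrocyte"))
  pure <- mkExpr(c(g1 = 100, g2 = 50))
  # identity
  same <- fractionOfPure(pure, pure, ms, "astrocyte")
  expect_equal(same$mean, 100)
  expect_equal(same$sem, 0)
  # hand: ratios 30% and 20% -> 25.0 +/- 5.0 (sd = 7.071, n = 2)
  mixed <- mkExpr(c(g1 = 30, g2 = 10))
  f <- fractionOfPure(mixed, pure, ms, "astrocyte")
  expect_equal(f$mean, 25)
  expect_equal(f$sem, 5)
  expect_equal(f$n, 2L)
  # scale equivariance
  f3 <- fractionOfPure(3 * mixed, pure, ms, "astrocyte")
  expect_equal(f3$mean, 3 * f$mean)
  # zero-pure genes are excluded and counted
  pure0 <- mkExpr(c(g1 = 100, g2 = 0))
  f0 <- fractionOfPure(mixed, pure0, ms, "astrocyte")
  expect_identical(f0$excluded, 1L)
  expect_equal(f0$mean, 30)
})

test_that("sign-count enrichment matches the exact binomial sign test", {
  ms <- toyMarkerSet(c("g1", "g2", "g3"), rep("astrocyte", 3))
  ctrl <- c(g1 = 1, g2 = 2, g3 = 3)
  s <- signCountEnrichment(ctrl, ctrl + 1, ms, "astrocyte")
  expect_identical(s$nUp, 3L)                 # forced direction
  expect_identical(s$nDown, 0L)
  expect_equal(s$p, 2 * 0.5^3)                # exact two-sided binomial
  # all ties: not applicable
  tie <- signCountEnrichment(ctrl, ctrl, ms, "astrocyte")
  expect_identical(tie$nTies, 3L)
  expect_true(is.na(tie$p))
  # ties excluded from the test denominator
  mix <- signCountEnrichment(ctrl, c(g1 = 2, g2 = 2, g3 = 4), ms,
                             "astrocyte")
  expect_identical(mix$nUp, 2L)
  expect_identical(mix$nTies, 1L)
  expect_equal(mix$p, 0.5)                    # 2 of 2 non-ties up: 2 * 0.5^2
  expect_error(signCountEnrichment(ctrl, ctrl, toyMarkerSet(character(0),
                                                            character(0)),
                                   "astrocyte"), "empty")
})

test_that("paired t on marker means matches the closed form", {
  ms <- toyMarkerSet(c("g1", "g2", "g3"), rep("neuron", 3))
  # identical pairs: t = 0, p = 1
  x <- c(g1 = 1, g2 = 2, g3 = 3)
  r0 <- pairedT(x, x, ms, "neuron")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # hand: diffs (-2, -3, -1), t = -2 / (1 / sqrt(3)) = -3.464, df = 2
  ctrl <- c(g1 = 10, g2 = 20, g3 = 30)
  treat <- c(g1 = 12, g2 = 23, g3 = 31)
  r <- pairedT(ctrl, treat, ms, "neuron")
  expect_equal(r$t, -2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_identical(as.integer(r$df), 2L)
  o <- oraclePairedT(ctrl, treat)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  # zero-variance non-zero differences: infinite t flagged with p = 0
  inf <- pairedT(ctrl, ctrl + 5, ms, "neuron")
  expect_identical(inf$t, -Inf)
  expect_identical(inf$p, 0)
})

test_that("summary fold change distinguishes geometric and arithmetic modes", {
  ms <- toyMarkerSet(c("g1", "g2"), rep("astrocyte", 2))
  ctrl <- c(g1 = 1, g2 = 1)
  treat <- c(g1 = 2, g2 = 8)
  expect_equal(meanFoldChange(ctrl, treat, ms, "astrocyte")$fold, 4)
  expect_equal(meanFoldChange(ctrl, treat, ms, "astrocyte",
                              mode = "arithmetic")$fold, 5)
  expect_equal(meanFoldChange(ctrl, ctrl, ms, "astrocyte")$fold, 1)
  halves <- meanFoldChange(ctrl, ctrl / 2, ms, "astrocyte")
  expect_equal(halves$fold, 2)                # reported as a decrease
  expect_identical(halves$direction, "decrease")
  doubled <- meanFoldChange(ctrl, 2 * ctrl, ms, "astrocyte",
                            mode = "arithmetic")
  expect_equal(doubled$fold, 2)
})

test_that("NNLS weight estimation is exact on noise-free mixtures", {
  ref <- generateReference(nGenes = 400, nEvents = 10, markerFrac = 0.5,
                           seed = 12)
  ms <- curateMarkers(profileExprMatrix(ref$neuron),
                      profileExprMatrix(ref$astrocyte))
  # pure sample
  wPure <- estimateWeights(geneExpr(ref$neuron), ref, ms)
  expect_equal(unname(wPure["neuron"]), 1, tolerance = 1e-10)
  # exact recovery at 85/15
  mixed <- 0.85 * geneExpr(ref$neuron) + 0.15 * geneExpr(ref$astrocyte)
  w <- estimateWeights(mixed, ref, ms)
  expect_equal(as.numeric(w), c(0.85, 0.15), tolerance = 1e-10)
  expect_lt(attr(w, "residual"), 1e-8)
})

test_that("weight estimation stays within 0.02 under log-normal expression noise", {
  ref <- generateReference(nGenes = 500, nEvents = 10, markerFrac = 0.4,
                           seed = 30)
  ms <- curateMarkers(profileExprMatrix(ref$neuron),
                      profileExprMatrix(ref$astrocyte))
  expect_gte(nrow(ms@table), 200L)
  err <- vapply(1:25, function(s) {
    smp <- mixBulkSample(ref, c(neuron = 0.85, astrocyte = 0.15),
                         depth = 500, exprNoiseSd = 0.2, seed = s)
    w <- estimateWeights(smp$expr, ref, ms)
    abs(w[["neuron"]] - 0.85)
  }, numeric(1))
  expect_lt(mean(err), 0.02)
})

test_that("nearly collinear pure profiles are flagged as ill-conditioned", {
  set.seed(4)
  genes <- sprintf("g%02d", 1:20)
  e <- stats::setNames(stats::rlnorm(20, 3, 1), genes)
  profs <- list(CellTypeProfile("neuron", e),
                CellTypeProfile("astrocyte", e * 1.0000001))
  ms <- toyMarkerSet(genes[1:10], rep(c("neuron", "astrocyte"), 5))
  expect_warning(w <- estimateWeights(e, profs, ms), "collinear")
  expect_true(attr(w, "illConditioned"))
})

test_that("a simulated neuron-death experiment raises the astrocyte weight and sweeps the sign counts", {
  ref <- generateReference(nGenes = 600, nEvents = 50, markerFrac = 0.3,
                           seed = 17)
  design <- MixtureDesign(replicates = 3L, depth = 500)
  ex <- simulateExperiment(ref, design, seed = 17, exprNoiseSd = 0.2)
  ms <- curateMarkers(profileExprMatrix(ref$neuron),
                      profileExprMatrix(ref$astrocyte))
  conds <- rep(design@conditions, each = 3)
  rep <- auditComposition(exprTable(ex), conds, "control", "treated",
                          ref, ms)
  w <- estimatedWeights(rep)
  expect_gt(w["astrocyte", "treated"], w["astrocyte", "control"])
  sc <- rep@signCounts$astrocyte
  expect_identical(sc$nUp, sc$nTotal)
  expect_lt(sc$p, 1e-6)
  # neuron markers move the other way
  expect_gt(rep@signCounts$neuron$nDown, 0.9 * rep@signCounts$neuron$nTotal)
  expect_identical(rep@meanFold$astrocyte$direction, "increase")
  expect_identical(rep@meanFold$neuron$direction, "decrease")
})
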