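test_that("reference generation plants exactly the requested marker and divergence structure", {
  ref <- generateReference(nGenes = 1000, nEvents = 200, markerFrac = 0.2,
                           psiDivergenceFrac = 0.5, seed = 42)
  gn <- geneExpr(ref$neuron); ga <- geneExpr(ref$astrocyte)
  # brute-force re-scan of the emitted tables against the curation rule
  isMarker <- (gn > 10 & gn >= 10 * ga) | (ga > 10 & ga >= 10 * gn)
  expect_identical(sum(isMarker), 200L)
  dpsi <- abs(eventPsi(ref$neuron) - eventPsi(ref$astrocyte))
  expect_identical(sum(dpsi >= 0.5), 100L)
  # flagship event carries the hallmark isoform-ratio values
  expect_equal(eventPsi(ref$neuron)[["Nrxn1_SS4"]], 0.28 / 1.28)
  expect_equal(eventPsi(ref$astrocyte)[["Nrxn1_SS4"]], 36 / 37)
  expect_equal(abs(eventPsi(ref$astrocyte)[["Nrxn1_SS4"]] -
                   eventPsi(ref$neuron)[["Nrxn1_SS4"]]), 0.754,
               tolerance = 1e-3)
  expect_identical(eventGene(ref$neuron)[["Nrxn1_SS4"]], "Nrxn1")
  # every event maps to a gene with expression defined (validity holds)
  expect_true(validObject(ref$neuron))
  # determinism
  ref2 <- generateReference(nGenes = 1000, nEvents = 200, markerFrac = 0.2,
                            psiDivergenceFrac = 0.5, seed = 42)
  expect_identical(geneExpr(ref2$astrocyte), ga)
  expect_identical(eventPsi(ref2$neuron), eventPsi(ref$neuron))
})

test_that("markerFrac = 0 yields no curatable markers and bad arguments error", {
  ref <- generateReference(nGenes = 50, nEvents = 5, markerFrac = 0, seed = 1)
  ms <- curateMarkers(profileExprMatrix(ref$neuron),
                      profileExprMatrix(ref$astrocyte))
  expect_identical(nrow(ms@table), 0L)
  expect_error(generateReference(nGenes = 5, nEvents = 1), "nGenes")
  expect_error(generateReference(nGenes = 50, nEvents = 0), "nEvents")
  expect_error(generateReference(nGenes = 50, nEvents = 5, markerFrac = 1.2),
               "markerFrac")
})

test_that("mixture PSI closed form matches brute-force transcript counting", {
  # hand example: flagship event at 85/15 with 2:1 expression
  psi <- psiFromRatio(c(0.28, 36))
  expect_equal(mixturePsi(c(0.85, 0.15), c(2, 1), psi),
               (0.85 * 2 * psi[1] + 0.15 * 1 * psi[2]) / (0.85 * 2 + 0.15),
               tolerance = 1e-15)
  expect_equal(mixturePsi(c(0.85, 0.15), c(2, 1), psi), 0.2800,
               tolerance = 1e-3)
  set.seed(7)
  for (i in 1:300) {
    k <- sample(2:4, 1)
    w <- stats::runif(k); w <- w / sum(w)
    g <- stats::runif(k, 0, 50)
    p <- stats::runif(k)
    expect_equal(mixturePsi(w, g, p), bruteForceMixturePsi(w, g, p),
                 tolerance = 1e-12)
  }
})

test_that("raising the high-PSI cell type's weight never decreases mixture PSI", {
  set.seed(11)
  for (i in 1:100) {
    g <- stats::runif(2, 0.1, 20)
    p <- sort(stats::runif(2))           # type 2 has the higher PSI
    wHi <- stats::runif(1)
    grid <- sort(c(wHi, stats::runif(5)))
    vals <- vapply(grid, function(w2) mixturePsi(c(1 - w2, w2), g, p),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-14))
  }
})

test_that("a mixed bulk sample has mixture expression, binomial counts and a determinism contract", {
  ref <- generateReference(nGenes = 60, nEvents = 15, seed = 3)
  w <- c(neuron = 0.85, astrocyte = 0.15)
  s1 <- mixBulkSample(ref, w, depth = 500, seed = 9)
  s2 <- mixBulkSample(ref, w, depth = 500, seed = 9)
  expect_identical(s1, s2)
  # noise-free expression is the weighted profile sum
  expected <- 0.85 * geneExpr(ref$neuron) + 0.15 * geneExpr(ref$astrocyte)
  expect_equal(s1$expr, expected, tolerance = 1e-12)
  # pure sample reproduces the profile PSI exactly
  pure <- mixBulkSample(ref, c(neuron = 1, astrocyte = 0), depth = 500,
                        seed = 9)
  expect_equal(pure$events$psi_mix, unname(eventPsi(ref$neuron)),
               tolerance = 1e-12)
  expect_error(mixBulkSample(ref, c(neuron = 0.9, astrocyte = 0.2)),
               "sum to 1")
})

test_that("events on genes with zero pooled expression are emitted with zero counts", {
  prof <- list(
    CellTypeProfile("neuron", c(gA = 5, gB = 0),
                    c(e1 = 0.4, e2 = 0.6), c(e1 = "gA", e2 = "gB")),
    CellTypeProfile("astrocyte", c(gA = 1, gB = 0),
                    c(e1 = 0.9, e2 = 0.1), c(e1 = "gA", e2 = "gB")))
  s <- mixBulkSample(prof, c(neuron = 0.5, astrocyte = 0.5), depth = 1000,
                     seed = 1)
  expect_identical(s$events$I[s$events$event_id == "e2"], 0L)
  expect_identical(s$events$S[s$events$event_id == "e2"], 0L)
  expect_true(is.nan(s$events$psi_mix[2]))
})

test_that("length-corrected junction counts converge to the mixture truth at high depth", {
  ref <- generateReference(nGenes = 100, nEvents = 30, seed = 5)
  w <- c(neuron = 0.7, astrocyte = 0.3)
  s <- mixBulkSample(ref, w, depth = 1e6, seed = 21)
  est <- computePsi(s$events$I, s$events$S,
                    s$events$IncFormLen, s$events$SkipFormLen)
  deep <- (s$events$I + s$events$S) >= 1e5
  expect_gt(sum(deep), 5)
  expect_true(all(abs(est[deep] - s$events$psi_mix[deep]) < 0.01))
})

test_that("a simulated experiment has the right cardinality, truth table and seed reproducibility", {
  ref <- generateReference(nGenes = 80, nEvents = 100, seed = 2)
  design <- MixtureDesign(replicates = 3L, depth = 300)
  ex <- simulateExperiment(ref, design, seed = 10)
  expect_identical(dim(inclusionCounts(eventCounts(ex))), c(100L, 6L))
  # 100 events x (2 conditions x 3 replicates) = 600 count records
  expect_identical(length(inclusionCounts(eventCounts(ex))), 600L)
  expect_identical(dim(mixtureTruth(ex)), c(100L, 2L))
  ex2 <- simulateExperiment(ref, design, seed = 10)
  expect_identical(exprTable(ex), exprTable(ex2))
  expect_identical(inclusionCounts(eventCounts(ex)),
                   inclusionCounts(eventCounts(ex2)))
  # identical weights in both conditions: truth delta-PSI is exactly 0
  flat <- MixtureDesign(weights = list(
    control = c(neuron = 0.85, astrocyte = 0.15),
    treated = c(neuron = 0.85, astrocyte = 0.15)), replicates = 2L)
  exFlat <- simulateExperiment(ref, flat, seed = 1)
  expect_equal(mixtureTruth(exFlat)[, 1], mixtureTruth(exFlat)[, 2],
               tolerance = 1e-15)
})

test_that("truth delta-PSI under an equal-expression composition shift matches hand arithmetic", {
  prof <- list(
    CellTypeProfile("neuron", c(Nrxn1 = 1),
                    c(Nrxn1_SS4 = psiFromRatio(0.28)),
                    c(Nrxn1_SS4 = "Nrxn1")),
    CellTypeProfile("astrocyte", c(Nrxn1 = 1),
                    c(Nrxn1_SS4 = psiFromRatio(36)),
                    c(Nrxn1_SS4 = "Nrxn1")))
  design <- MixtureDesign(replicates = 1L)
  ex <- simulateExperiment(prof, design, seed = 1)
  dTruth <- mixtureTruth(ex)["Nrxn1_SS4", "treated"] -
    mixtureTruth(ex)["Nrxn1_SS4", "control"]
  expect_equal(dTruth, 0.2639, tolerance = 1e-3)
})
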