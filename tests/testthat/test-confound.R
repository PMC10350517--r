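evTab <- function(ids, d) data.frame(event_id = ids, delta_psi = d)

test_that("delta-delta correlation reproduces identity and hand Pearson/OLS", {
  ids <- c("a", "b", "c")
  # lm warns about the perfect fit on exact identity input; that is expected
  idt <- suppressWarnings(
    deltaDeltaCorrelation(evTab(ids, c(1, 2, 3)), evTab(ids, c(1, 2, 3))))
  expect_equal(idt@r, 1)
  expect_equal(idt@slope, 1)
  # hand: x = (1,2,3), y = (1,2,4) -> r = 0.9820, slope = 1.5
  r <- deltaDeltaCorrelation(evTab(ids, c(1, 2, 4)), evTab(ids, c(1, 2, 3)))
  expect_equal(r@r, 0.9820, tolerance = 1e-4)
  expect_equal(r@slope, 1.5)
  expect_identical(r@nEvents, 3L)
  expect_true(r@rCI95[1] <= r@r && r@r <= r@rCI95[2])
  # fewer than 3 matched pairs is insufficient data
  expect_error(deltaDeltaCorrelation(evTab(c("a", "b"), 1:2),
                                     evTab(c("a", "b"), 2:1)), "at least 3")
  # zero variance flags r as undefined
  flat <- deltaDeltaCorrelation(evTab(ids, c(1, 1, 1)),
                                evTab(ids, c(1, 2, 3)))
  expect_true(is.na(flat@r))
})

test_that("delta-delta correlation agrees with textbook closed forms on random instances", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    ids <- sprintf("e%03d", seq_len(n))
    x <- stats::rnorm(n); y <- 0.5 * x + stats::rnorm(n, sd = 0.3)
    rep <- deltaDeltaCorrelation(evTab(ids, y), evTab(ids, x))
    o <- oraclePearson(x, y)
    expect_equal(rep@r, o$r, tolerance = 1e-12)
    expect_equal(rep@p, o$p, tolerance = 1e-12)
    expect_equal(rep@rCI95, o$ci95, tolerance = 1e-12)
    expect_equal(rep@slope, oracleSlope(x, y), tolerance = 1e-12)
  }
})

test_that("unmatched events are dropped and counted, never imputed", {
  cond <- evTab(c("a", "b", "c", "onlyCond"), c(1, 2, 4, 9))
  ct <- evTab(c("a", "b", "c", "onlyCt", "alsoCt"), c(1, 2, 3, 9, 9))
  r <- deltaDeltaCorrelation(cond, ct)
  expect_identical(r@nEvents, 3L)
  expect_identical(unname(r@unmatched), c(1L, 2L))
})

test_that("the permutation null is exact for identity and calibrated for independent noise", {
  x <- 1:20 / 10
  expect_equal(permutationNull(x, x, nPerm = 999, seed = 1), 1 / 1000)
  expect_true(is.na(permutationNull(x, rep(1, 20), nPerm = 999, seed = 1)))
  # under independence the rejection rate at 0.05 stays near 0.05
  set.seed(40)
  rej <- vapply(1:200, function(s) {
    x <- stats::rnorm(50); y <- stats::rnorm(50)
    permutationNull(x, y, nPerm = 199, seed = s) <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  # deterministic given seed
  set.seed(1); x <- stats::rnorm(30); y <- stats::rnorm(30)
  expect_identical(permutationNull(x, y, nPerm = 499, seed = 7),
                   permutationNull(x, y, nPerm = 499, seed = 7))
})

test_that("mixture-model predictions of apparent delta-PSI follow the closed form", {
  ref <- generateReference(nGenes = 80, nEvents = 40, seed = 14)
  w <- c(neuron = 0.85, astrocyte = 0.15)
  # no shift: all predictions are exactly zero
  none <- predictMixtureDeltaPsi(ref, w, w)
  expect_true(all(none$delta_psi == 0))
  # flagship with equal expression: hand value 0.2639
  prof <- list(
    CellTypeProfile("neuron", c(Nrxn1 = 1),
                    c(Nrxn1_SS4 = psiFromRatio(0.28)),
                    c(Nrxn1_SS4 = "Nrxn1")),
    CellTypeProfile("astrocyte", c(Nrxn1 = 1),
                    c(Nrxn1_SS4 = psiFromRatio(36)),
                    c(Nrxn1_SS4 = "Nrxn1")))
  p <- predictMixtureDeltaPsi(prof, w, c(neuron = 0.5, astrocyte = 0.5))
  expect_equal(p$delta_psi, 0.2639, tolerance = 1e-3)
  # raising the astrocyte weight moves every event toward the astrocyte PSI
  shift <- predictMixtureDeltaPsi(ref, w, c(neuron = 0.5, astrocyte = 0.5))
  nz <- shift$psi_diff_celltype != 0
  expect_true(all(sign(shift$delta_psi[nz]) ==
                  sign(shift$psi_diff_celltype[nz])))
})

test_that("composition-shift regression has slope = weight change in the equal-expression limit", {
  set.seed(31)
  nEv <- 30
  genes <- sprintf("g%02d", seq_len(nEv))
  psiN <- stats::runif(nEv); psiA <- stats::runif(nEv)
  evs <- stats::setNames(genes, sprintf("e%02d", seq_len(nEv)))
  eq <- stats::setNames(rep(5, nEv), genes)
  prof <- list(CellTypeProfile("neuron", eq, stats::setNames(psiN, names(evs)), evs),
               CellTypeProfile("astrocyte", eq, stats::setNames(psiA, names(evs)), evs))
  r <- compositionShiftRegression(prof,
                                  c(neuron = 0.85, astrocyte = 0.15),
                                  c(neuron = 0.50, astrocyte = 0.50))
  expect_equal(r$slope, 0.35, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)
  # no shift: slope 0
  r0 <- compositionShiftRegression(prof,
                                   c(neuron = 0.85, astrocyte = 0.15),
                                   c(neuron = 0.85, astrocyte = 0.15))
  expect_equal(r0$slope, 0, tolerance = 1e-12)
})

test_that("expression heterogeneity attenuates events unevenly, pulling r below 1", {
  set.seed(32)
  nEv <- 60
  genes <- sprintf("g%02d", seq_len(nEv))
  evs <- stats::setNames(genes, sprintf("e%02d", seq_len(nEv)))
  gN <- stats::setNames(stats::rlnorm(nEv, 2, 1), genes)
  gA <- stats::setNames(stats::rlnorm(nEv, 2, 1), genes)
  prof <- list(
    CellTypeProfile("neuron", gN,
                    stats::setNames(stats::runif(nEv), names(evs)), evs),
    CellTypeProfile("astrocyte", gA,
                    stats::setNames(stats::runif(nEv), names(evs)), evs))
  wC <- c(neuron = 0.85, astrocyte = 0.15)
  wT <- c(neuron = 0.50, astrocyte = 0.50)
  r <- compositionShiftRegression(prof, wC, wT)
  expect_lt(r$r, 1)
  expect_gt(r$r, 0)
  # per-event attenuation factors bound the regression slope
  tab <- r$table
  att <- tab$delta_psi / tab$psi_diff_celltype
  att <- att[is.finite(att)]
  expect_gt(r$slope, min(att) - 1e-9)
  expect_lt(r$slope, max(att) + 1e-9)
})
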