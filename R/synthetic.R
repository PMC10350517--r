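#' Generate two-cell-type reference profiles
#'
#' Builds a pair of [CellTypeProfile-class] objects emulating pure neuronal
#' and pure astrocytic cultures: a stated fraction of genes are cell-type
#' specific (expression strictly above `minFpkm` in the high type and at
#' least `minFold`-fold above the other type, split evenly between the two
#' types), and a stated fraction of splice events diverge strongly between
#' the types (|psi difference| >= 0.5).  One flagship skipped-exon event,
#' `Nrxn1_SS4`, always carries the hallmark values of Nrxn1 splice-site 4:
#' isoform ratio 0.28 in neurons versus 36 in astrocytes (psi 0.21875 vs
#' 0.97297), on a gene expressed twice as highly in neurons as in
#' astrocytes.  Deterministic given `seed`.
#'
#' @param nGenes number of genes (>= 10); includes the flagship gene.
#' @param nEvents number of splice events (>= 1); includes the flagship.
#' @param markerFrac fraction of genes made cell-type specific, in [0, 1].
#'   Exactly `round(markerFrac * nGenes)` genes satisfy the specificity rule.
#' @param psiDivergenceFrac fraction of events with |psi_A - psi_B| >= 0.5,
#'   in [0, 1] (the flagship counts towards it).
#' @param seed integer seed.
#' @param minFpkm,minFold the specificity thresholds the markers are planted
#'   to satisfy (defaults 10 and 10).
#' @return named list with elements `neuron` and `astrocyte`, each a
#'   [CellTypeProfile-class].
#' @examples
#' ref <- generateReference(nGenes = 100, nEvents = 20, seed = 1)
#' eventPsi(ref$neuron)[["Nrxn1_SS4"]]   # 0.21875
#' @export
generateReference <- function(nGenes = 1000, nEvents = 200,
                              markerFrac = 0.2, psiDivergenceFrac = 0.5,
                              seed = 1L, minFpkm = 10, minFold = 10) {
  stopIf(nGenes < 10 || nEvents < 1, "nGenes >= 10 and nEvents >= 1 required")
  stopIf(markerFrac < 0 || markerFrac > 1 ||
         psiDivergenceFrac < 0 || psiDivergenceFrac > 1,
         "markerFrac and psiDivergenceFrac must lie in [0, 1]")
  nMark <- round(markerFrac * nGenes)
  stopIf(nMark > nGenes - 1, "markerFrac leaves no room for the flagship gene")

  set.seed(as.integer(seed))
  genes <- c("Nrxn1", sprintf("gene%05d", seq_len(nGenes - 1L)))
  exprN <- exprA <- numeric(nGenes)
  names(exprN) <- names(exprA) <- genes
  # Flagship: neurons express the gene 2x astrocytes (damps the net-ratio
  # shift when astrocytes take over), and neither value passes the marker
  # floor, so the flagship never counts as a marker.
  exprN["Nrxn1"] <- 2
  exprA["Nrxn1"] <- 1

  idx <- seq(2L, nGenes)
  markIdx <- if (nMark) sample(idx, nMark) else integer(0)
  restIdx <- setdiff(idx, markIdx)
  nN <- ceiling(nMark / 2)                       # neuron-specific share
  neuronIdx <- markIdx[seq_len(nN)]
  astroIdx <- setdiff(markIdx, neuronIdx)
  plantMarker <- function(n, fpkm, fold) {
    hi <- exp(stats::runif(n, log(fpkm * 1.2), log(fpkm * 30)))
    lo <- hi / (fold * exp(stats::runif(n, 0.05, 1.6)))
    list(hi = hi, lo = lo)
  }
  if (length(neuronIdx)) {
    m <- plantMarker(length(neuronIdx), minFpkm, minFold)
    exprN[neuronIdx] <- m$hi; exprA[neuronIdx] <- m$lo
  }
  if (length(astroIdx)) {
    m <- plantMarker(length(astroIdx), minFpkm, minFold)
    exprA[astroIdx] <- m$hi; exprN[astroIdx] <- m$lo
  }
  if (length(restIdx)) {
    # shared genes: fold strictly below minFold in either direction
    base <- exp(stats::runif(length(restIdx), log(0.5), log(200)))
    fold <- exp(stats::runif(length(restIdx), 0, log(minFold * 0.8)))
    flip <- stats::runif(length(restIdx)) < 0.5
    exprN[restIdx] <- ifelse(flip, base * sqrt(fold), base / sqrt(fold))
    exprA[restIdx] <- ifelse(flip, base / sqrt(fold), base * sqrt(fold))
  }

  events <- c("Nrxn1_SS4",
              if (nEvents > 1) sprintf("event%05d", seq_len(nEvents - 1L)))
  psiN <- psiA <- numeric(nEvents)
  names(psiN) <- names(psiA) <- events
  psiN["Nrxn1_SS4"] <- psiFromRatio(0.28)
  psiA["Nrxn1_SS4"] <- psiFromRatio(36)
  nDiv <- max(round(psiDivergenceFrac * nEvents) - 1L, 0L)  # flagship counts
  if (nEvents > 1) {
    others <- seq(2L, nEvents)
    divIdx <- if (nDiv) sample(others, min(nDiv, length(others))) else integer(0)
    sameIdx <- setdiff(others, divIdx)
    if (length(divIdx)) {
      lo <- stats::runif(length(divIdx), 0, 0.2)
      hi <- stats::runif(length(divIdx), 0.75, 1)
      flip <- stats::runif(length(divIdx)) < 0.5
      psiN[divIdx] <- ifelse(flip, lo, hi)
      psiA[divIdx] <- ifelse(flip, hi, lo)
    }
    if (length(sameIdx)) {
      p <- stats::runif(length(sameIdx))
      d <- stats::runif(length(sameIdx), -0.3, 0.3)
      psiN[sameIdx] <- p
      psiA[sameIdx] <- pmin(pmax(p + d, 0), 1)
    }
  }
  evGene <- c("Nrxn1",
              if (nEvents > 1)
                sample(genes[-1], nEvents - 1L, replace = nEvents - 1L > nGenes - 1L))
  names(evGene) <- events

  list(
    neuron = CellTypeProfile("neuron", exprN, psiN, evGene),
    astrocyte = CellTypeProfile("astrocyte", exprA, psiA, evGene)
  )
}

#' Mix one bulk sample from pure cell-type profiles
#'
#' Pools mRNA from the supplied profiles with the given mass weights.  Gene
#' expression is the weighted sum \eqn{\sum_t w_t g_t}, optionally perturbed
#' by multiplicative log-normal noise.  For each splice event the pooled
#' inclusion fraction is [mixturePsi()]; junction reads are then drawn as
#' n ~ Poisson(depth x g_mix / mean(g_mix)) total reads, split
#' I ~ Binomial(n, psi_mix l_I / (psi_mix l_I + (1 - psi_mix) l_S)),
#' S = n - I, so events on highly expressed genes receive more reads.
#' Deterministic given `seed`.
#'
#' @param profiles list of [CellTypeProfile-class] objects sharing gene and
#'   event universes.
#' @param weights named numeric vector of mRNA-mass weights, one per profile
#'   (matched by cell-type label), summing to 1.
#' @param depth expected junction reads for an average-expression event.
#' @param exprNoiseSd sdlog of multiplicative log-normal expression noise;
#'   0 (default) disables it, leaving binomial counting noise only.
#' @param incFormLen,skipFormLen effective lengths of the inclusion and
#'   skipping forms (junction equivalents; defaults 2 and 1), recycled per
#'   event.
#' @param seed integer seed.
#' @return list with `expr` (named numeric vector) and `events` (data.frame
#'   event_id, gene_id, I, S, IncFormLen, SkipFormLen, psi_mix).  Events on
#'   genes with zero pooled expression are emitted with I = S = 0 and
#'   psi_mix = NaN.
#' @examples
#' ref <- generateReference(nGenes = 50, nEvents = 10, seed = 1)
#' s <- mixBulkSample(ref, c(neuron = 0.85, astrocyte = 0.15),
#'                    depth = 1000, seed = 7)
#' head(s$events)
#' @export
mixBulkSample <- function(profiles, weights, depth = 2000, exprNoiseSd = 0,
                          incFormLen = 2, skipFormLen = 1, seed = 1L) {
  stopIf(abs(sum(weights) - 1) > 1e-12, "weights must sum to 1")
  stopIf(any(weights < 0), "weights must be non-negative")
  stopIf(depth <= 0, "depth must be positive")
  labs <- vapply(profiles, cellType, character(1))
  names(profiles) <- labs
  stopIf(!all(names(weights) %in% labs),
         "weights must be named by the profiles' cell types")
  genes <- names(geneExpr(profiles[[1]]))
  evGene <- eventGene(profiles[[1]])
  g <- matrix(unlist(lapply(profiles, geneExpr)), ncol = length(profiles),
              dimnames = list(genes, labs))            # gene x type
  psi <- matrix(unlist(lapply(profiles, eventPsi)), ncol = length(profiles),
                dimnames = list(names(evGene), labs))  # event x type
  w <- weights[colnames(g)]

  set.seed(as.integer(seed))
  expr <- as.numeric(g %*% w)
  names(expr) <- rownames(g)
  if (exprNoiseSd > 0)
    expr <- expr * stats::rlnorm(length(expr), -exprNoiseSd^2 / 2, exprNoiseSd)

  nEv <- length(evGene)
  lI <- rep_len(incFormLen, nEv)
  lS <- rep_len(skipFormLen, nEv)
  gEv <- g[unname(evGene), , drop = FALSE]         # event x type expression
  tot <- as.numeric(gEv %*% w)
  psiMix <- ifelse(tot > 0, as.numeric((gEv * psi) %*% w) / tot, NaN)
  scale <- mean(tot)
  n <- ifelse(tot > 0,
              stats::rpois(nEv, depth * tot / ifelse(scale > 0, scale, 1)),
              0L)
  pRead <- ifelse(tot > 0,
                  psiMix * lI / (psiMix * lI + (1 - psiMix) * lS), 0)
  I <- stats::rbinom(nEv, n, pRead)
  I[tot == 0] <- 0L
  S <- as.integer(n - I)
  list(
    expr = expr,
    events = data.frame(
      event_id = names(evGene), gene_id = unname(evGene),
      I = as.integer(I), S = S,
      IncFormLen = lI, SkipFormLen = lS,
      psi_mix = psiMix, row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Simulate a full mixing experiment
#'
#' Composes [mixBulkSample()] over every (condition, replicate) cell of a
#' [MixtureDesign-class], emulating a mixed-culture study in which a
#' treatment shifts the cell-type composition (e.g. excitotoxic neuronal
#' death after a depolarising stimulus) without altering within-cell-type
#' splicing.  Per-sample random substreams are derived deterministically
#' from `(seed, condition, replicate)`, so the experiment is reproducible
#' and individual samples are independent of how many others are drawn.
#'
#' @param profiles list of two [CellTypeProfile-class] objects (see
#'   [generateReference()]).
#' @param design a [MixtureDesign-class].
#' @param seed integer master seed.
#' @param exprNoiseSd,incFormLen,skipFormLen passed to [mixBulkSample()].
#' @return a [SyntheticExperiment-class]; `truth` holds the noise-free
#'   mixture PSI per event and condition.
#' @examples
#' ref <- generateReference(nGenes = 60, nEvents = 12, seed = 1)
#' ex <- simulateExperiment(ref, MixtureDesign(replicates = 2L), seed = 1)
#' ex
#' @export
simulateExperiment <- function(profiles, design, seed = 1L, exprNoiseSd = 0,
                               incFormLen = 2, skipFormLen = 1) {
  validObject(design)
  labs <- vapply(profiles, cellType, character(1))
  genes <- names(geneExpr(profiles[[1]]))
  evGene <- eventGene(profiles[[1]])
  nEv <- length(evGene)
  sampleNames <- unlist(lapply(design@conditions, function(cond)
    sprintf("%s_rep%d", cond, seq_len(design@replicates))))
  conds <- rep(design@conditions, each = design@replicates)

  expr <- matrix(0, length(genes), length(sampleNames),
                 dimnames = list(genes, sampleNames))
  inc <- skp <- matrix(0L, nEv, length(sampleNames),
                       dimnames = list(names(evGene), sampleNames))
  lI <- rep_len(incFormLen, nEv)
  lS <- rep_len(skipFormLen, nEv)
  k <- 0L
  for (cond in design@conditions) {
    for (r in seq_len(design@replicates)) {
      k <- k + 1L
      s <- mixBulkSample(profiles, design@weights[[cond]],
                         depth = design@depth, exprNoiseSd = exprNoiseSd,
                         incFormLen = lI, skipFormLen = lS,
                         seed = sampleSeed(seed, cond, r))
      expr[, k] <- s$expr[genes]
      inc[, k] <- s$events$I
      skp[, k] <- s$events$S
    }
  }
  truth <- matrix(NA_real_, nEv, length(design@conditions),
                  dimnames = list(names(evGene), design@conditions))
  for (cond in design@conditions) {
    w <- design@weights[[cond]]
    truth[, cond] <- vapply(names(evGene), function(ev) {
      g <- vapply(profiles, function(p) geneExpr(p)[[evGene[[ev]]]],
                  numeric(1))
      p <- vapply(profiles, function(p) eventPsi(p)[[ev]], numeric(1))
      mixturePsi(w[labs], g, p)
    }, numeric(1))
  }
  truth[is.nan(truth)] <- 0   # zero-expression events carry no signal

  counts <- SpliceEventCounts(inc, skp, geneId = unname(evGene),
                              incFormLen = lI, skipFormLen = lS,
                              condition = conds)
  new("SyntheticExperiment", profiles = profiles, design = design,
      exprTable = expr, eventCounts = counts,
      truth = truth, seed = as.integer(seed))
}
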