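#' Expression of marker genes as a fraction of their pure-culture level
#'
#' For each marker gene of `cellType`, the mean FPKM across the mixed
#' samples is expressed as a percentage of its mean across the pure
#' reference samples; the summary is the mean of these per-gene ratios with
#' its SEM over genes.  A value well above zero indicates that the mixed
#' culture contains a substantial contribution from that cell type.  Genes
#' with a zero pure-culture mean are excluded and counted.
#'
#' @param mixed,pure numeric gene x sample FPKM matrices.
#' @param markers a [MarkerSet-class].
#' @param cellType which marker set to use.
#' @return list: `mean`, `sem` (percent), `n` genes used, `excluded` count,
#'   plus `ratioOfMeans` (sum of mixed means / sum of pure means x 100), an
#'   alternative pooled statistic.
#' @examples
#' m <- matrix(c(30, 10), 2, 1, dimnames = list(c("g1", "g2"), "mix1"))
#' p <- matrix(c(100, 50), 2, 1, dimnames = list(c("g1", "g2"), "pure1"))
#' ms <- new("MarkerSet",
#'   table = data.frame(gene_id = c("g1", "g2"), cell_type = "astrocyte",
#'                      mean_high = NA_real_, mean_low = NA_real_,
#'                      fold = NA_real_),
#'   criteria = list(minFpkm = 10, minFold = 10), provenance = "toy")
#' fractionOfPure(m, p, ms, "astrocyte")   # 25.0 +/- 5.0 %
#' @export
fractionOfPure <- function(mixed, pure, markers, cellType) {
  genes <- markerGenes(markers, cellType)
  genes <- intersect(genes, intersect(rownames(mixed), rownames(pure)))
  stopIf(!length(genes), "no usable marker genes for cell type '%s'", cellType)
  mMix <- rowMeans(as.matrix(mixed)[genes, , drop = FALSE])
  mPure <- rowMeans(as.matrix(pure)[genes, , drop = FALSE])
  ok <- mPure > 0
  stopIf(!any(ok), "all marker genes have zero pure-culture expression")
  ratio <- 100 * mMix[ok] / mPure[ok]
  n <- sum(ok)
  list(mean = mean(ratio),
       sem = if (n > 1) stats::sd(ratio) / sqrt(n) else 0,
       n = n, excluded = sum(!ok),
       ratioOfMeans = 100 * sum(mMix[ok]) / sum(mPure[ok]))
}

marker_pairs <- function(ctrlMeans, treatMeans, markers, cellType) {
  genes <- markerGenes(markers, cellType)
  stopIf(!length(genes), "empty marker set for cell type '%s'", cellType)
  genes <- intersect(genes, intersect(names(ctrlMeans), names(treatMeans)))
  stopIf(!length(genes), "no marker genes present in both mean vectors")
  list(ctrl = ctrlMeans[genes], treat = treatMeans[genes], genes = genes)
}

#' Sign-count enrichment of marker genes across conditions
#'
#' Counts how many marker genes moved up versus down between paired
#' condition means and tests the split against an exact two-sided binomial
#' sign test (p = 0.5, ties excluded).  In a composition-shift scenario,
#' markers of the surviving cell type rise almost unanimously.
#'
#' @param ctrlMeans,treatMeans named numeric vectors of per-gene condition
#'   means (e.g. mean FPKM across replicates).
#' @param markers a [MarkerSet-class].
#' @param cellType which marker set to count.
#' @return list: `nUp`, `nDown`, `nTies`, `nTotal`, `p` (NA when all pairs
#'   tie).
#' @export
signCountEnrichment <- function(ctrlMeans, treatMeans, markers, cellType) {
  pr <- marker_pairs(ctrlMeans, treatMeans, markers, cellType)
  up <- pr$treat > pr$ctrl
  down <- pr$treat < pr$ctrl
  nUp <- sum(up); nDown <- sum(down)
  p <- if (nUp + nDown == 0) NA_real_ else
    stats::binom.test(nUp, nUp + nDown, p = 0.5,
                      alternative = "two.sided")$p.value
  list(nUp = nUp, nDown = nDown, nTies = length(up) - nUp - nDown,
       nTotal = length(up), p = p)
}

#' Paired t-test on marker-gene condition means
#'
#' Classic paired two-sided t-test on per-gene (control - treated)
#' differences across the marker genes, df = n - 1.
#'
#' @inheritParams signCountEnrichment
#' @return list: `t`, `df`, `p`; when the differences have zero variance and
#'   a non-zero mean, `t` is +/-Inf with p reported as 0.
#' @export
pairedT <- function(ctrlMeans, treatMeans, markers = NULL, cellType = NULL) {
  if (!is.null(markers)) {
    pr <- marker_pairs(ctrlMeans, treatMeans, markers, cellType)
    ctrlMeans <- pr$ctrl; treatMeans <- pr$treat
  }
  stopIf(length(ctrlMeans) < 2, "need at least 2 pairs")
  d <- ctrlMeans - treatMeans
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = length(d) - 1L, p = 1))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0))
  }
  ht <- stats::t.test(ctrlMeans, treatMeans, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Summary fold change of marker genes between conditions
#'
#' @inheritParams signCountEnrichment
#' @param mode `"geometric"` (default; exp of the mean log fold) or
#'   `"arithmetic"` (mean of per-gene folds).  Genes with a zero mean in
#'   either condition are excluded and counted.
#' @return list: `fold` (>= 1), `direction` (`"increase"`/`"decrease"`/
#'   `"none"`), `mode`, `nUsed`, `excluded`.
#' @export
meanFoldChange <- function(ctrlMeans, treatMeans, markers, cellType,
                           mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  pr <- marker_pairs(ctrlMeans, treatMeans, markers, cellType)
  ok <- pr$ctrl > 0 & pr$treat > 0
  stopIf(!any(ok), "all marker genes excluded (zero means)")
  fc <- pr$treat[ok] / pr$ctrl[ok]
  m <- if (mode == "geometric") exp(mean(log(fc))) else mean(fc)
  direction <- if (m > 1) "increase" else if (m < 1) "decrease" else "none"
  list(fold = if (m >= 1) m else 1 / m, direction = direction,
       mode = mode, nUsed = sum(ok), excluded = sum(!ok))
}

#' Estimate cell-type mRNA-mass weights by non-negative least squares
#'
#' Fits the mixed sample's marker-gene expression as a non-negative
#' combination of the pure profiles, \eqn{\min_{w \ge 0} \sum_g (m_g -
#' \sum_t w_t p_{t,g})^2}, then normalises the weights to sum to 1 so they
#' read as fractions of total mRNA mass.
#'
#' @param mixed named numeric vector (or single-column matrix) of the mixed
#'   sample's expression.
#' @param pureProfiles list of [CellTypeProfile-class] objects, or a gene x
#'   cell-type matrix of pure-population expression.
#' @param markers a [MarkerSet-class]; the fit uses the union of all marker
#'   genes (>= 2 per cell type required).
#' @return named numeric weight vector summing to 1, with attributes
#'   `residual` (root-mean-square residual of the fit) and `illConditioned`
#'   (TRUE, with a warning, when the marker profiles are nearly collinear).
#' @examples
#' ref <- generateReference(nGenes = 100, nEvents = 5, seed = 1)
#' mk <- curateMarkers(matrix(geneExpr(ref$neuron),
#'                            dimnames = list(names(geneExpr(ref$neuron)), "n")),
#'                     matrix(geneExpr(ref$astrocyte),
#'                            dimnames = list(names(geneExpr(ref$astrocyte)), "a")))
#' s <- mixBulkSample(ref, c(neuron = 0.85, astrocyte = 0.15), seed = 2)
#' estimateWeights(s$expr, ref, mk)
#' @export
estimateWeights <- function(mixed, pureProfiles, markers) {
  if (is.list(pureProfiles) && !is.matrix(pureProfiles)) {
    P <- vapply(pureProfiles, geneExpr, geneExpr(pureProfiles[[1]]))
    colnames(P) <- vapply(pureProfiles, cellType, character(1))
  } else P <- as.matrix(pureProfiles)
  if (is.matrix(mixed)) mixed <- mixed[, 1]
  perType <- table(markers@table$cell_type)
  stopIf(length(perType) < 2 || any(perType < 2),
         "need at least 2 markers per cell type")
  genes <- intersect(markerGenes(markers),
                     intersect(names(mixed), rownames(P)))
  stopIf(length(genes) < ncol(P), "too few marker genes shared with profiles")
  A <- P[genes, , drop = FALSE]
  b <- mixed[genes]
  illCond <- FALSE
  cn <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cn) || cn > 1e8) {
    warning("pure profiles are nearly collinear on the marker genes; ",
            "weight estimates are ill-conditioned")
    illCond <- TRUE
  }
  fit <- pracma::lsqnonneg(A, b)
  w <- fit$x
  names(w) <- colnames(P)
  stopIf(sum(w) == 0, "degenerate fit: all weights zero")
  wn <- w / sum(w)
  attr(wn, "residual") <- sqrt(mean((b - as.numeric(A %*% w))^2))
  attr(wn, "illConditioned") <- illCond
  wn
}

#' Run the marker-based composition audit for one contrast
#'
#' Convenience wrapper assembling a [CompositionReport-class]: per-cell-type
#' fraction-of-pure statistics (mixed control samples vs pure references),
#' sign counts, paired t and summary fold change between control and
#' treated means, and NNLS weight estimates per condition.
#'
#' @param mixed numeric gene x sample matrix of the mixed experiment.
#' @param conditions per-sample condition labels for `mixed`'s columns.
#' @param ctrl,treat the two condition labels to contrast.
#' @param pureProfiles list of [CellTypeProfile-class] objects (or gene x
#'   cell-type matrix) of pure references.
#' @param markers a [MarkerSet-class].
#' @return a [CompositionReport-class].
#' @export
auditComposition <- function(mixed, conditions, ctrl, treat,
                             pureProfiles, markers) {
  mixed <- as.matrix(mixed)
  stopIf(!all(c(ctrl, treat) %in% conditions),
         "conditions must contain both contrast labels")
  ctrlMeans <- rowMeans(mixed[, conditions == ctrl, drop = FALSE])
  treatMeans <- rowMeans(mixed[, conditions == treat, drop = FALSE])
  if (is.list(pureProfiles) && !is.matrix(pureProfiles)) {
    P <- vapply(pureProfiles, geneExpr, geneExpr(pureProfiles[[1]]))
    colnames(P) <- vapply(pureProfiles, cellType, character(1))
  } else P <- as.matrix(pureProfiles)
  types <- intersect(unique(markers@table$cell_type), colnames(P))
  fop <- lapply(types, function(ct)
    fractionOfPure(mixed[, conditions == ctrl, drop = FALSE],
                   P[, ct, drop = FALSE], markers, ct))
  names(fop) <- types
  sc <- lapply(types, function(ct)
    signCountEnrichment(ctrlMeans, treatMeans, markers, ct))
  names(sc) <- types
  pt <- lapply(types, function(ct)
    pairedT(ctrlMeans, treatMeans, markers, ct))
  names(pt) <- types
  mf <- lapply(types, function(ct)
    meanFoldChange(ctrlMeans, treatMeans, markers, ct))
  names(mf) <- types
  w <- vapply(c(ctrl, treat), function(cond)
    estimateWeights(rowMeans(mixed[, conditions == cond, drop = FALSE]),
                    P, markers),
    numeric(ncol(P)))
  new("CompositionReport", fractionOfPure = fop, signCounts = sc,
      pairedT = pt, meanFold = mf, weights = w)
}
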