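#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' Per-cell-type expression and exon-inclusion profile
#'
#' A \code{CellTypeProfile} holds, for one pure cell population, mean gene
#' expression on an FPKM-like scale (arbitrary units per unit of mRNA mass)
#' and the percent-spliced-in value \eqn{\psi \in [0, 1]} of each alternative
#' exon, together with the gene each event belongs to.  Two such profiles are
#' the ground truth of the two-component mRNA mixture model.
#'
#' @slot cellType single character label, e.g. \code{"neuron"}.
#' @slot geneExpr named numeric vector of non-negative expression values;
#'   names are gene identifiers.
#' @slot eventPsi named numeric vector of inclusion fractions in
#'   \eqn{[0, 1]}; names are event identifiers.
#' @slot eventGene named character vector mapping event identifiers to gene
#'   identifiers; every gene must appear in \code{geneExpr}.
#'
#' @seealso [generateReference()], [mixBulkSample()], [psiFromRatio()]
#' @export
setClass("CellTypeProfile",
  representation(
    cellType = "character",
    geneExpr = "numeric",
    eventPsi = "numeric",
    eventGene = "character"
  )
)

setValidity("CellTypeProfile", function(object) {
  msg <- character()
  if (length(object@cellType) != 1L || is.na(object@cellType))
    msg <- c(msg, "cellType must be a single non-NA label")
  if (is.null(names(object@geneExpr)) || anyDuplicated(names(object@geneExpr)))
    msg <- c(msg, "geneExpr must be named with unique gene ids")
  if (any(object@geneExpr < 0) || anyNA(object@geneExpr))
    msg <- c(msg, "geneExpr values must be finite and >= 0")
  if (length(object@eventPsi)) {
    if (is.null(names(object@eventPsi)) ||
        anyDuplicated(names(object@eventPsi)))
      msg <- c(msg, "eventPsi must be named with unique event ids")
    if (anyNA(object@eventPsi) ||
        any(object@eventPsi < 0 | object@eventPsi > 1))
      msg <- c(msg, "eventPsi values must lie in [0, 1]")
    if (!identical(names(object@eventPsi), names(object@eventGene)))
      msg <- c(msg, "eventPsi and eventGene must share names in order")
    if (!all(object@eventGene %in% names(object@geneExpr)))
      msg <- c(msg, "every event must map to a gene with expression defined")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellTypeProfile
#'
#' @param cellType cell-type label.
#' @param geneExpr named non-negative numeric vector of expression values.
#' @param eventPsi named numeric vector of inclusion fractions in [0, 1].
#' @param eventGene named character vector, event id to gene id.
#' @return A [CellTypeProfile-class] object.
#' @examples
#' CellTypeProfile("neuron",
#'   geneExpr = c(Nrxn1 = 2),
#'   eventPsi = c(Nrxn1_SS4 = psiFromRatio(0.28)),
#'   eventGene = c(Nrxn1_SS4 = "Nrxn1"))
#' @export
CellTypeProfile <- function(cellType, geneExpr, eventPsi = numeric(0),
                            eventGene = character(0)) {
  new("CellTypeProfile", cellType = as.character(cellType),
      geneExpr = geneExpr, eventPsi = eventPsi, eventGene = eventGene)
}

#' Mixture design: per-condition mRNA-mass weights
#'
#' Describes a mixing experiment over conditions: for each condition the
#' fraction of total mRNA mass contributed by each cell type (the
#' confounder), the number of replicates, and the sequencing depth scale
#' (expected junction reads for an event whose gene has average expression).
#' Weights are fractions of mRNA mass, not of cell counts; see
#' [cellCountsToWeights()] to convert.
#'
#' @slot conditions character vector of condition labels.
#' @slot weights named list, one element per condition, each a named numeric
#'   vector of non-negative weights summing to 1 (tolerance 1e-12).
#' @slot replicates integer, replicates per condition (>= 1).
#' @slot depth numeric, expected junction reads per average-expression event.
#' @export
setClass("MixtureDesign",
  representation(
    conditions = "character",
    weights = "list",
    replicates = "integer",
    depth = "numeric"
  )
)

setValidity("MixtureDesign", function(object) {
  msg <- character()
  if (!length(object@conditions) || anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be non-empty and unique")
  if (!identical(sort(names(object@weights)), sort(object@conditions)))
    msg <- c(msg, "weights must have one element per condition")
  for (cond in names(object@weights)) {
    w <- object@weights[[cond]]
    if (is.null(names(w)) || anyNA(w) || any(w < 0))
      msg <- c(msg, sprintf("weights[%s] must be named and >= 0", cond))
    else if (abs(sum(w) - 1) > 1e-12)
      msg <- c(msg, sprintf("weights[%s] must sum to 1 within 1e-12", cond))
  }
  if (length(object@replicates) != 1L || object@replicates < 1L)
    msg <- c(msg, "replicates must be a single integer >= 1")
  if (length(object@depth) != 1L || object@depth <= 0)
    msg <- c(msg, "depth must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureDesign
#'
#' Defaults emulate a mixed cortical culture contributing 85% neuronal and
#' 15% astrocytic mRNA under control conditions, with a neurotoxic treatment
#' that halves the culture's neuronal contribution (50/50 after treatment)
#' while leaving astrocytes untouched.
#'
#' @param conditions condition labels.
#' @param weights named list of per-condition named weight vectors
#'   (fractions of total mRNA mass; each sums to 1).
#' @param replicates replicates per condition.
#' @param depth expected junction reads per average-expression event.
#' @return A [MixtureDesign-class] object.
#' @examples
#' MixtureDesign()
#' @export
MixtureDesign <- function(conditions = c("control", "treated"),
                          weights = list(
                            control = c(neuron = 0.85, astrocyte = 0.15),
                            treated = c(neuron = 0.50, astrocyte = 0.50)),
                          replicates = 3L, depth = 2000) {
  new("MixtureDesign", conditions = conditions, weights = weights,
      replicates = as.integer(replicates), depth = as.numeric(depth))
}

#' Inclusion/skipping junction counts per splice event and sample
#'
#' Extends \code{SummarizedExperiment} with two integer assays,
#' \code{inclusion} and \code{skipping}, holding junction read counts per
#' event (row) and sample (column).  \code{rowData} carries \code{GeneID} and
#' the effective form lengths \code{IncFormLen} and \code{SkipFormLen} used
#' for length-normalised PSI; \code{colData} carries the sample
#' \code{condition}.
#'
#' @seealso [SpliceEventCounts()], [computePsi()], [deltaPsiTest()],
#'   [readRmatsTable()]
#' @export
setClass("SpliceEventCounts", contains = "SummarizedExperiment")

setValidity("SpliceEventCounts", function(object) {
  msg <- character()
  an <- names(assays(object))
  if (!all(c("inclusion", "skipping") %in% an))
    msg <- c(msg, "assays must include 'inclusion' and 'skipping'")
  else {
    for (a in c("inclusion", "skipping")) {
      x <- assay(object, a)
      if (anyNA(x) || any(x < 0) || any(x != round(x)))
        msg <- c(msg, sprintf("assay '%s' must hold non-negative integers", a))
    }
  }
  rd <- rowData(object)
  need <- c("GeneID", "IncFormLen", "SkipFormLen")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must have GeneID, IncFormLen and SkipFormLen")
  else if (any(rd$IncFormLen <= 0) || any(rd$SkipFormLen <= 0))
    msg <- c(msg, "effective form lengths must be positive")
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must have a 'condition' column")
  if (length(msg)) msg else TRUE
})

#' Construct a SpliceEventCounts object
#'
#' @param inclusion,skipping integer matrices (event x sample) of inclusion
#'   and skipping junction reads; same dimensions, rownames are event ids.
#' @param geneId character vector of gene ids, one per event.
#' @param incFormLen,skipFormLen positive effective lengths, recycled across
#'   events (defaults 2 and 1 junction equivalents: skipped-exon topology has
#'   two inclusion junctions and one skipping junction).
#' @param condition character vector of per-sample condition labels.
#' @return A [SpliceEventCounts-class] object.
#' @examples
#' inc <- matrix(c(30L, 10L), 1, 2, dimnames = list("ev1", c("s1", "s2")))
#' skp <- matrix(c(10L, 30L), 1, 2, dimnames = list("ev1", c("s1", "s2")))
#' SpliceEventCounts(inc, skp, geneId = "GeneX",
#'                   condition = c("control", "treated"))
#' @export
SpliceEventCounts <- function(inclusion, skipping, geneId,
                              incFormLen = 2, skipFormLen = 1,
                              condition = rep("sample", ncol(inclusion))) {
  stopifnot(identical(dim(inclusion), dim(skipping)))
  n <- nrow(inclusion)
  storage.mode(inclusion) <- "integer"
  storage.mode(skipping) <- "integer"
  rd <- DataFrame(GeneID = rep_len(geneId, n),
                  IncFormLen = rep_len(as.numeric(incFormLen), n),
                  SkipFormLen = rep_len(as.numeric(skipFormLen), n))
  cd <- DataFrame(condition = rep_len(condition, ncol(inclusion)),
                  row.names = colnames(inclusion))
  se <- SummarizedExperiment(
    assays = list(inclusion = inclusion, skipping = skipping),
    rowData = rd, colData = cd)
  new("SpliceEventCounts", se)
}

#' Curated set of cell-type-specific marker genes
#'
#' Holds genes passing a dual-threshold specificity rule (expression above a
#' floor in the high cell type, and at least a stated fold higher than in the
#' other type), together with the criteria and a provenance note identifying
#' the reference tables used.
#'
#' @slot table data.frame with columns \code{gene_id}, \code{cell_type},
#'   \code{mean_high}, \code{mean_low}, \code{fold} (Inf when the low type
#'   has zero mean).
#' @slot criteria list with \code{minFpkm} and \code{minFold}.
#' @slot provenance character note on the reference tables.
#' @seealso [curateMarkers()], [restrictToExpressed()], [markerGenes()]
#' @export
setClass("MarkerSet",
  representation(table = "data.frame", criteria = "list",
                 provenance = "character")
)

setValidity("MarkerSet", function(object) {
  msg <- character()
  need <- c("gene_id", "cell_type", "mean_high", "mean_low", "fold")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("table must have columns:", paste(need, collapse = ", ")))
  else if (anyDuplicated(object@table$gene_id))
    msg <- c(msg, "duplicate gene ids in marker table")
  if (!all(c("minFpkm", "minFold") %in% names(object@criteria)))
    msg <- c(msg, "criteria must contain minFpkm and minFold")
  else if (object@criteria$minFpkm <= 0 || object@criteria$minFold <= 0)
    msg <- c(msg, "criteria thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' A simulated two-cell-type mixing experiment
#'
#' Bundles the generating profiles and design with the emitted gene x sample
#' expression table, per-event junction counts, and the noise-free mixture
#' truth (per-event mixture PSI per condition).  Regenerating with the same
#' seed reproduces identical tables.
#'
#' @slot profiles list of two [CellTypeProfile-class] objects.
#' @slot design the [MixtureDesign-class] used.
#' @slot exprTable numeric gene x sample matrix (FPKM scale).
#' @slot eventCounts a [SpliceEventCounts-class] with one column per sample.
#' @slot truth numeric event x condition matrix of noise-free mixture PSI.
#' @slot seed integer seed the experiment was generated from.
#' @seealso [simulateExperiment()]
#' @export
setClass("SyntheticExperiment",
  representation(
    profiles = "list",
    design = "MixtureDesign",
    exprTable = "matrix",
    eventCounts = "SpliceEventCounts",
    truth = "matrix",
    seed = "integer"
  )
)

setValidity("SyntheticExperiment", function(object) {
  msg <- character()
  if (length(object@profiles) != 2L ||
      !all(vapply(object@profiles, is, logical(1), "CellTypeProfile")))
    msg <- c(msg, "profiles must be a list of two CellTypeProfile objects")
  if (any(object@exprTable < 0))
    msg <- c(msg, "expression table must be non-negative")
  if (anyNA(object@truth) || any(object@truth < 0 | object@truth > 1))
    msg <- c(msg, "truth PSI must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Composition audit report
#'
#' Collects the marker-based composition proxies for one control/treated
#' contrast: fraction-of-pure expression, per-marker-set sign counts with an
#' exact sign test, paired t statistics, summary fold changes, and
#' NNLS-estimated mRNA-mass weights per condition.
#'
#' @slot fractionOfPure list per cell type (mean, sem, n, excluded).
#' @slot signCounts list per marker set (nUp, nDown, nTies, nTotal, p).
#' @slot pairedT list per marker set (t, df, p).
#' @slot meanFold list per marker set (fold, direction, mode, nUsed).
#' @slot weights numeric cell-type x condition matrix of estimated mRNA
#'   fractions (columns sum to 1).
#' @seealso [auditComposition()]
#' @export
setClass("CompositionReport",
  representation(
    fractionOfPure = "list",
    signCounts = "list",
    pairedT = "list",
    meanFold = "list",
    weights = "matrix"
  )
)

setValidity("CompositionReport", function(object) {
  msg <- character()
  w <- object@weights
  if (length(w)) {
    if (any(w < -1e-9 | w > 1 + 1e-9))
      msg <- c(msg, "estimated weights must lie in [0, 1]")
    if (any(abs(colSums(w) - 1) > 1e-6))
      msg <- c(msg, "estimated weights must sum to 1 per condition")
  }
  if (length(msg)) msg else TRUE
})

#' Delta-delta correlation diagnostic report
#'
#' The headline diagnostic: across splice events, the condition-wise change
#' in inclusion (y) is compared with the cell-type-wise difference in
#' inclusion (x).  A strong correlation with a slope below 1 indicates that
#' an apparent condition effect is an attenuated image of the cell-type
#' difference, i.e. a composition confound.
#'
#' @slot nEvents number of matched events.
#' @slot r Pearson correlation.
#' @slot rCI95 Fisher-z 95% confidence interval for r.
#' @slot p parametric two-sided p for r.
#' @slot slope OLS slope of condition delta-PSI on cell-type delta-PSI.
#' @slot slopeCI95 95% confidence interval for the slope.
#' @slot pPerm permutation p for r (NA unless computed).
#' @slot matchedEvents character vector of matched event ids.
#' @slot unmatched named integer vector: events dropped on each side.
#' @slot scatter data.frame (event_id, x, y) behind the fit.
#' @seealso [deltaDeltaCorrelation()], [permutationNull()]
#' @export
setClass("ConfoundReport",
  representation(
    nEvents = "integer",
    r = "numeric",
    rCI95 = "numeric",
    p = "numeric",
    slope = "numeric",
    slopeCI95 = "numeric",
    pPerm = "numeric",
    matchedEvents = "character",
    unmatched = "integer",
    scatter = "data.frame"
  )
)

setValidity("ConfoundReport", function(object) {
  msg <- character()
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (!anyNA(object@rCI95) && !is.na(object@r) &&
      (object@r < object@rCI95[1] - 1e-9 || object@r > object@rCI95[2] + 1e-9))
    msg <- c(msg, "confidence interval must contain r")
  if (length(msg)) msg else TRUE
})
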