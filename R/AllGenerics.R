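#' @rdname CellTypeProfile-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname CellTypeProfile-class
#' @export
setGeneric("geneExpr", function(x) standardGeneric("geneExpr"))

#' @rdname CellTypeProfile-class
#' @export
setGeneric("eventPsi", function(x) standardGeneric("eventPsi"))

#' @rdname CellTypeProfile-class
#' @export
setGeneric("eventGene", function(x) standardGeneric("eventGene"))

#' @rdname SpliceEventCounts-class
#' @export
setGeneric("inclusionCounts", function(x) standardGeneric("inclusionCounts"))

#' @rdname SpliceEventCounts-class
#' @export
setGeneric("skippingCounts", function(x) standardGeneric("skippingCounts"))

#' Marker genes in a MarkerSet
#'
#' @param x a [MarkerSet-class].
#' @param cellType optional label; restrict to markers of that cell type.
#' @return character vector of gene ids.
#' @export
setGeneric("markerGenes", function(x, cellType = NULL)
  standardGeneric("markerGenes"))

#' @rdname SyntheticExperiment-class
#' @export
setGeneric("exprTable", function(x) standardGeneric("exprTable"))

#' @rdname SyntheticExperiment-class
#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' @rdname SyntheticExperiment-class
#' @export
setGeneric("mixtureTruth", function(x) standardGeneric("mixtureTruth"))

#' @rdname CompositionReport-class
#' @export
setGeneric("estimatedWeights", function(x) standardGeneric("estimatedWeights"))
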