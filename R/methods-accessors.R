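#' @rdname CellTypeProfile-class
#' @export
setMethod("cellType", "CellTypeProfile", function(x) x@cellType)

#' @rdname CellTypeProfile-class
#' @export
setMethod("geneExpr", "CellTypeProfile", function(x) x@geneExpr)

#' @rdname CellTypeProfile-class
#' @export
setMethod("eventPsi", "CellTypeProfile", function(x) x@eventPsi)

#' @rdname CellTypeProfile-class
#' @export
setMethod("eventGene", "CellTypeProfile", function(x) x@eventGene)

#' @rdname SpliceEventCounts-class
#' @param x a SpliceEventCounts object.
#' @export
setMethod("inclusionCounts", "SpliceEventCounts",
          function(x) assay(x, "inclusion"))

#' @rdname SpliceEventCounts-class
#' @export
setMethod("skippingCounts", "SpliceEventCounts",
          function(x) assay(x, "skipping"))

#' @rdname markerGenes
#' @export
setMethod("markerGenes", "MarkerSet", function(x, cellType = NULL) {
  tab <- x@table
  if (!is.null(cellType)) tab <- tab[tab$cell_type == cellType, , drop = FALSE]
  tab$gene_id
})

#' @rdname SyntheticExperiment-class
#' @export
setMethod("exprTable", "SyntheticExperiment", function(x) x@exprTable)

#' @rdname SyntheticExperiment-class
#' @export
setMethod("eventCounts", "SyntheticExperiment", function(x) x@eventCounts)

#' @rdname SyntheticExperiment-class
#' @export
setMethod("mixtureTruth", "SyntheticExperiment", function(x) x@truth)

#' @rdname CompositionReport-class
#' @export
setMethod("estimatedWeights", "CompositionReport", function(x) x@weights)

setMethod("show", "CellTypeProfile", function(object) {
  cat("CellTypeProfile:", object@cellType, "\n",
      " genes: ", length(object@geneExpr),
      "  events: ", length(object@eventPsi), "\n", sep = "")
})

setMethod("show", "MixtureDesign", function(object) {
  cat("MixtureDesign with", length(object@conditions), "conditions,",
      object@replicates, "replicate(s) each, depth", object@depth, "\n")
  for (cond in object@conditions) {
    w <- object@weights[[cond]]
    cat(sprintf("  %s: %s\n", cond,
                paste(sprintf("%s=%.3f", names(w), w), collapse = ", ")))
  }
})

setMethod("show", "MarkerSet", function(object) {
  tab <- object@table
  cat("MarkerSet:", nrow(tab), "genes",
      sprintf("(minFpkm > %g, fold >= %g)\n",
              object@criteria$minFpkm, object@criteria$minFold))
  if (nrow(tab)) print(table(tab$cell_type))
  if (length(object@provenance) && nzchar(object@provenance[1]))
    cat("provenance:", object@provenance[1], "\n")
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat("SyntheticExperiment (seed ", object@seed, ")\n",
      "  ", nrow(object@exprTable), " genes x ", ncol(object@exprTable),
      " samples; ", nrow(object@eventCounts), " splice events\n", sep = "")
  show(object@design)
})

setMethod("show", "CompositionReport", function(object) {
  cat("CompositionReport\n")
  if (length(object@fractionOfPure)) {
    for (ct in names(object@fractionOfPure)) {
      f <- object@fractionOfPure[[ct]]
      cat(sprintf("  fraction of pure %s: %.1f +/- %.1f%% (n = %d genes)\n",
                  ct, f$mean, f$sem, f$n))
    }
  }
  for (ct in names(object@signCounts)) {
    s <- object@signCounts[[ct]]
    cat(sprintf("  %s markers: %d/%d up (sign test p = %.3g)\n",
                ct, s$nUp, s$nTotal, s$p))
  }
  if (length(object@weights)) {
    cat("  estimated mRNA-mass weights:\n")
    print(round(object@weights, 4))
  }
})

setMethod("show", "ConfoundReport", function(object) {
  cat("ConfoundReport on", object@nEvents, "matched events\n")
  cat(sprintf("  Pearson r = %.4f (95%% CI %.4f to %.4f), p = %.3g\n",
              object@r, object@rCI95[1], object@rCI95[2], object@p))
  cat(sprintf("  OLS slope = %.4f (95%% CI %.4f to %.4f)\n",
              object@slope, object@slopeCI95[1], object@slopeCI95[2]))
  if (!is.na(object@pPerm))
    cat(sprintf("  permutation p = %.3g\n", object@pPerm))
  if (sum(object@unmatched))
    cat("  unmatched events dropped:",
        paste(sprintf("%s=%d", names(object@unmatched), object@unmatched),
              collapse = ", "), "\n")
})
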