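#' Curate cell-type-specific marker genes from pure reference expression
#'
#' A gene is specific to cell type A when its mean expression across A's
#' replicate samples is strictly greater than `minFpkm` and at least
#' `minFold` times its mean in the other type (and symmetrically for B).
#' When the other type's mean is zero the fold is infinite, so the gene is
#' specific provided it passes the expression floor.  Fold changes are taken
#' on replicate means with no pseudocount: a thresholding rule should not be
#' sensitive to an arbitrary offset.
#'
#' @param refA,refB numeric gene x sample matrices of FPKM for the two pure
#'   populations (rownames are gene ids).  Their gene intersection is used.
#' @param cellTypeA,cellTypeB labels for the two populations.
#' @param minFpkm expression floor in the high type (strict >; default 10).
#' @param minFold minimum fold over the other type (>=; default 10).
#' @return a [MarkerSet-class].
#' @examples
#' refN <- matrix(c(100, 50, 2), 3, 1, dimnames = list(c("A", "B", "C"), "n1"))
#' refA <- matrix(c(5, 8, 40), 3, 1, dimnames = list(c("A", "B", "C"), "a1"))
#' curateMarkers(refN, refA)   # A neuron-specific, C astrocyte-specific
#' @export
curateMarkers <- function(refA, refB, cellTypeA = "neuron",
                          cellTypeB = "astrocyte",
                          minFpkm = 10, minFold = 10) {
  stopIf(minFpkm <= 0 || minFold <= 0, "thresholds must be positive")
  refA <- as.matrix(refA); refB <- as.matrix(refB)
  stopIf(any(refA < 0) || any(refB < 0), "expression tables must be >= 0")
  common <- intersect(rownames(refA), rownames(refB))
  stopIf(!length(common), "reference tables share no genes")
  mA <- rowMeans(refA[common, , drop = FALSE])
  mB <- rowMeans(refB[common, , drop = FALSE])
  foldA <- ifelse(mB == 0, ifelse(mA > 0, Inf, NA_real_), mA / mB)
  foldB <- ifelse(mA == 0, ifelse(mB > 0, Inf, NA_real_), mB / mA)
  isA <- !is.na(foldA) & mA > minFpkm & foldA >= minFold
  isB <- !is.na(foldB) & mB > minFpkm & foldB >= minFold
  tab <- rbind(
    data.frame(gene_id = common[isA],
               cell_type = rep(cellTypeA, sum(isA)),
               mean_high = mA[isA], mean_low = mB[isA], fold = foldA[isA]),
    data.frame(gene_id = common[isB],
               cell_type = rep(cellTypeB, sum(isB)),
               mean_high = mB[isB], mean_low = mA[isB], fold = foldB[isB]))
  rownames(tab) <- NULL
  new("MarkerSet", table = tab,
      criteria = list(minFpkm = minFpkm, minFold = minFold),
      provenance = sprintf("curated from %d shared genes (%s: %d samples, %s: %d samples)",
                           length(common), cellTypeA, ncol(refA),
                           cellTypeB, ncol(refB)))
}

#' Restrict a marker set to genes robustly expressed in a target data set
#'
#' Keeps the markers whose mean FPKM over the scoped samples of `target`
#' exceeds `minFpkm`.  By default the scope is the control samples only:
#' when auditing a treatment suspected of shifting composition, the treated
#' samples' marker expression is itself the quantity under test and should
#' not gate the gene list.
#'
#' @param markers a [MarkerSet-class].
#' @param target numeric gene x sample matrix.
#' @param conditions character vector of per-sample condition labels for
#'   `target`'s columns.
#' @param scope condition label(s) defining the samples to average over, or
#'   `"all"`; default the first condition (control).
#' @param minFpkm expression floor (strict >; default 10).
#' @return a [MarkerSet-class]; dropped genes are counted in an attribute
#'   `dropped`, and markers absent from `target` are dropped too.
#' @export
restrictToExpressed <- function(markers, target,
                                conditions = rep("all", ncol(target)),
                                scope = conditions[1], minFpkm = 10) {
  target <- as.matrix(target)
  use <- if (identical(scope, "all")) rep(TRUE, ncol(target))
         else conditions %in% scope
  stopIf(!any(use), "scope '%s' matches no sample", paste(scope, collapse = ","))
  tab <- markers@table
  if (!nrow(tab)) return(markers)
  present <- tab$gene_id %in% rownames(target)
  m <- rowMeans(target[tab$gene_id[present], use, drop = FALSE])
  keep <- present
  keep[present] <- m > minFpkm
  out <- new("MarkerSet", table = tab[keep, , drop = FALSE],
             criteria = markers@criteria,
             provenance = c(markers@provenance,
                            sprintf("restricted to mean FPKM > %g in scope [%s]",
                                    minFpkm, paste(scope, collapse = ","))))
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Read or write a marker set as two-column TSV
#'
#' @param markers a [MarkerSet-class].
#' @param path TSV path (columns gene_id, cell_type on write; at least those
#'   on read).
#' @return `readMarkerSet` returns a [MarkerSet-class] (summary statistics
#'   NA; criteria recorded as supplied).
#' @param minFpkm,minFold criteria to record on read.
#' @export
writeMarkerSet <- function(markers, path) {
  utils::write.table(markers@table[, c("gene_id", "cell_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMarkerSet
#' @export
readMarkerSet <- function(path, minFpkm = 10, minFold = 10) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopIf(!all(c("gene_id", "cell_type") %in% colnames(tab)),
         "marker TSV needs gene_id and cell_type columns")
  tab$mean_high <- tab$mean_low <- tab$fold <- NA_real_
  new("MarkerSet", table = tab[, c("gene_id", "cell_type", "mean_high",
                                   "mean_low", "fold")],
      criteria = list(minFpkm = minFpkm, minFold = minFold),
      provenance = paste("read from", path))
}
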