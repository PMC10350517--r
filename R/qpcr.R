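#' Efficiency-corrected relative quantity from qPCR Ct values
#'
#' Efficiency-corrected delta-delta-Ct: with amplification efficiency e
#' (fraction per cycle; 99% -> base E = 1.99), the expression of the target
#' in a sample relative to a calibrator sample, normalised to a reference
#' gene, is
#' \deqn{E_t^{(Ct_{cal,t} - Ct_t)} / E_r^{(Ct_{cal,r} - Ct_r)}.}
#' With e = 1 for both primer pairs this reduces exactly to the classic
#' \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ctTarget,ctCalTarget target-gene Ct in the sample and calibrator.
#' @param ctRef,ctCalRef reference-gene Ct in the sample and calibrator.
#' @param eTarget,eRef primer-pair efficiencies as fractions in (0, 1.5]
#'   (default 0.99 as is typical of a validated assay).
#' @return relative expression (positive scalar, vectorised).
#' @examples
#' relativeQuantity(10, 12, 11, 12, eTarget = 1, eRef = 1)   # 2^2 / 2^1 = 2
#' @export
relativeQuantity <- function(ctTarget, ctCalTarget, ctRef, ctCalRef,
                             eTarget = 0.99, eRef = 0.99) {
  stopIf(any(c(eTarget, eRef) <= 0) || any(c(eTarget, eRef) > 1.5),
         "efficiencies must be fractions in (0, 1.5]")
  stopIf(any(c(ctTarget, ctCalTarget, ctRef, ctCalRef) <= 0),
         "Ct values must be positive")
  (1 + eTarget)^(ctCalTarget - ctTarget) / (1 + eRef)^(ctCalRef - ctRef)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample`, `target`, `ct`, `efficiency` (fraction per
#' cycle) and optionally `replicate`.  Targets are free-form labels; an
#' isoform panel uses `isoform_plus`, `isoform_minus` and `reference`
#' (e.g. SS4+, SS4- primer pairs and Rpl13a).  Rows with undetermined Ct
#' (empty or NA) are dropped with a count.
#'
#' @param path CSV path.
#' @return data.frame with the columns above; attribute `droppedUndetermined`
#'   counts removed rows.
#' @export
readCtTable <- function(path) {
  stopIf(!file.exists(path), "file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "ct", "efficiency")
  stopIf(!all(need %in% colnames(tab)), "Ct table needs columns: %s",
         paste(need, collapse = ", "))
  tab$ct <- suppressWarnings(as.numeric(tab$ct))
  bad <- is.na(tab$ct)
  out <- tab[!bad, , drop = FALSE]
  attr(out, "droppedUndetermined") <- sum(bad)
  out
}

meanCt <- function(panel, sample, target) {
  rows <- panel[panel$sample == sample & panel$target == target, ,
                drop = FALSE]
  if (!nrow(rows)) return(list(ct = NA_real_, e = NA_real_))
  list(ct = mean(rows$ct), e = rows$efficiency[1])
}

#' Isoform ratio of a sample from an isoform-specific qPCR panel
#'
#' Computes reference-normalised relative quantities for the
#' inclusion-specific (`isoform_plus`) and exclusion-specific
#' (`isoform_minus`) primer pairs and the within-sample isoform ratio
#' R = plus / minus (e.g. the SS4+/SS4- ratio).  Technical replicates are
#' averaged on the Ct scale before exponentiation.  Because both isoform
#' quantities within a sample share the reference gene and the calibrator
#' scaling, those factors cancel algebraically in the ratio, which reduces
#' to \eqn{R = E_+^{-Ct_+} / E_-^{-Ct_-}}; R is therefore exactly
#' calibrator-independent while the per-isoform relative quantities are
#' not.
#'
#' @param panel data.frame as from [readCtTable()].
#' @param sample sample label to quantify.
#' @param calibrator calibrator sample label (default: first sample in the
#'   panel); only the per-isoform relative quantities depend on it.
#' @return list: `sample`, `relativePlus`, `relativeMinus`, `ratio`
#'   (all NA, with `defined = FALSE`, when an isoform Ct is missing).
#' @export
isoformRatio <- function(panel, sample, calibrator = panel$sample[1]) {
  stopIf(!"reference" %in% panel$target[panel$sample == sample],
         "sample '%s' has no reference-gene wells", sample)
  ref <- meanCt(panel, sample, "reference")
  refCal <- meanCt(panel, calibrator, "reference")
  quant <- function(target) {
    t <- meanCt(panel, sample, target)
    tCal <- meanCt(panel, calibrator, target)
    if (is.na(t$ct) || is.na(tCal$ct)) return(NA_real_)
    relativeQuantity(t$ct, tCal$ct, ref$ct, refCal$ct, t$e, ref$e)
  }
  p <- quant("isoform_plus"); m <- quant("isoform_minus")
  plus <- meanCt(panel, sample, "isoform_plus")
  minus <- meanCt(panel, sample, "isoform_minus")
  if (is.na(plus$ct) || is.na(minus$ct))
    return(list(sample = sample, relativePlus = p, relativeMinus = m,
                ratio = NA_real_, defined = FALSE))
  ratio <- (1 + plus$e)^(-plus$ct) / (1 + minus$e)^(-minus$ct)
  list(sample = sample, relativePlus = p, relativeMinus = m,
       ratio = ratio, defined = TRUE)
}

#' Net isoform ratio of a pooled RNA sample
#'
#' When RNA from two sources with isoform ratios `Ra` and `Rb` is pooled,
#' each source contributes target-gene mRNA in amount `amountA` / `amountB`
#' (expression x mRNA mass).  Converting ratios to inclusion fractions
#' \eqn{\psi_i = R_i / (1 + R_i)}, the pooled ratio is
#' \deqn{R_{net} = \sum_i a_i \psi_i / \sum_i a_i (1 - \psi_i),}
#' always bounded between the two source ratios.  This is why killing the
#' low-ratio cell type (reducing its amount) raises the net ratio toward the
#' surviving type's value without any within-cell-type change.
#'
#' @param Ra,Rb positive isoform ratios of the two sources.
#' @param amountA,amountB non-negative target-gene mRNA amounts (not both
#'   zero).
#' @return net ratio (positive scalar).
#' @examples
#' netMixtureRatio(0.28, 36, 2 * 0.85, 1 * 0.15)   # 0.3889
#' @export
netMixtureRatio <- function(Ra, Rb, amountA, amountB) {
  stopIf(any(c(Ra, Rb) <= 0), "ratios must be positive")
  stopIf(any(c(amountA, amountB) < 0), "amounts must be non-negative")
  stopIf(amountA + amountB == 0, "both amounts are zero")
  psi <- psiFromRatio(c(Ra, Rb))
  a <- c(amountA, amountB)
  sum(a * psi) / sum(a * (1 - psi))
}
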