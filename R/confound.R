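#' Delta-delta correlation: condition-wise vs cell-type-wise splicing change
#'
#' The central diagnostic for composition confounding.  Events are matched
#' by identifier between a condition contrast (e.g. treated vs control in a
#' mixed culture) and a cell-type contrast (e.g. astrocytes vs neurons from
#' pure cultures).  With the cell-type difference on x and the condition
#' difference on y, a Pearson correlation near 1 combined with an OLS slope
#' strictly between 0 and 1 says the apparent condition effect is an
#' attenuated copy of the cell-type difference — the signature of a partial
#' composition shift rather than within-cell-type regulation.
#'
#' @param condEvents data.frame with columns `event_id` and `delta_psi` for
#'   the condition contrast (the y axis); typically a filtered
#'   [deltaPsiTest()] result.
#' @param cellTypeEvents same layout for the cell-type contrast (the x
#'   axis).
#' @param nPerm if > 0, also compute a permutation p for r via
#'   [permutationNull()].
#' @param seed seed for the permutation.
#' @return a [ConfoundReport-class].
#' @examples
#' cond <- data.frame(event_id = c("a", "b", "c"), delta_psi = c(1, 2, 4))
#' ct <- data.frame(event_id = c("a", "b", "c"), delta_psi = c(1, 2, 3))
#' deltaDeltaCorrelation(cond, ct)   # r = 0.9820, slope = 1.5
#' @export
deltaDeltaCorrelation <- function(condEvents, cellTypeEvents, nPerm = 0,
                                  seed = 1L) {
  for (nm in c("event_id", "delta_psi")) {
    stopIf(!nm %in% colnames(condEvents) || !nm %in% colnames(cellTypeEvents),
           "both inputs need an '%s' column", nm)
  }
  condEvents <- condEvents[!is.na(condEvents$delta_psi), , drop = FALSE]
  cellTypeEvents <- cellTypeEvents[!is.na(cellTypeEvents$delta_psi), ,
                                   drop = FALSE]
  ids <- intersect(condEvents$event_id, cellTypeEvents$event_id)
  unmatched <- c(condition = nrow(condEvents) - length(ids),
                 cellType = nrow(cellTypeEvents) - length(ids))
  stopIf(length(ids) < 3, "need at least 3 matched events, got %d",
         length(ids))
  y <- condEvents$delta_psi[match(ids, condEvents$event_id)]
  x <- cellTypeEvents$delta_psi[match(ids, cellTypeEvents$event_id)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new("ConfoundReport", nEvents = length(ids), r = NA_real_,
               rCI95 = c(NA_real_, NA_real_), p = NA_real_,
               slope = NA_real_, slopeCI95 = c(NA_real_, NA_real_),
               pPerm = NA_real_, matchedEvents = ids,
               unmatched = as.integer(unmatched),
               scatter = data.frame(event_id = ids, x = x, y = y)))
  }
  pc <- pearsonCI(x, y)
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = 0.95)
  pPerm <- if (nPerm > 0) permutationNull(x, y, nPerm = nPerm, seed = seed)
           else NA_real_
  rep <- new("ConfoundReport",
             nEvents = length(ids), r = pc$statistic, rCI95 = pc$ci95,
             p = pc$p, slope = unname(stats::coef(fit)["x"]),
             slopeCI95 = as.numeric(ci), pPerm = pPerm,
             matchedEvents = ids,
             unmatched = stats::setNames(as.integer(unmatched),
                                         names(unmatched)),
             scatter = data.frame(event_id = ids, x = x, y = y))
  rep
}

#' Permutation p-value for a Pearson correlation
#'
#' Permutes y relative to x `nPerm` times and counts permutations whose
#' |r| meets or exceeds the observed |r|:
#' p = (1 + #\{|r_perm| >= |r_obs|\}) / (nPerm + 1).  Deterministic given
#' `seed`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed.
#' @return permutation p, or NA when either vector is constant.
#' @export
permutationNull <- function(x, y, nPerm = 999, seed = 1L) {
  stopIf(nPerm < 100, "nPerm must be at least 100")
  stopIf(length(x) != length(y) || length(x) < 3,
         "x and y must be equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  rObs <- abs(stats::cor(x, y))
  set.seed(as.integer(seed))
  hits <- sum(vapply(seq_len(nPerm), function(i)
    abs(stats::cor(x, sample(y))) >= rObs - 1e-15, logical(1)))
  (1 + hits) / (nPerm + 1)
}

#' Predicted apparent delta-PSI under a pure composition shift
#'
#' With within-cell-type splicing unchanged, shifting the mRNA-mass weights
#' from `wCtrl` to `wTreat` changes each event's bulk inclusion fraction by
#' \eqn{\Delta\psi_{pred} = \psi_{mix}(w_{treat}) - \psi_{mix}(w_{ctrl})}
#' via the expression-weighted mixture formula.  This is the mechanistic
#' prediction the delta-delta diagnostic is compared against.
#'
#' @param profiles list of [CellTypeProfile-class] objects.
#' @param wCtrl,wTreat named weight vectors (fractions of mRNA mass,
#'   summing to 1, named by cell type).
#' @return data.frame: event_id, gene_id, psi_ctrl, psi_treat, delta_psi,
#'   and psi_diff_celltype (second profile minus first).
#' @export
predictMixtureDeltaPsi <- function(profiles, wCtrl, wTreat) {
  stopIf(abs(sum(wCtrl) - 1) > 1e-12 || abs(sum(wTreat) - 1) > 1e-12,
         "weights must sum to 1")
  labs <- vapply(profiles, cellType, character(1))
  stopIf(!all(labs %in% names(wCtrl)) || !all(labs %in% names(wTreat)),
         "weights must be named by the profiles' cell types")
  evGene <- eventGene(profiles[[1]])
  g <- matrix(unlist(lapply(profiles, function(p) geneExpr(p)[unname(evGene)])),
              ncol = length(profiles), dimnames = list(names(evGene), labs))
  psi <- matrix(unlist(lapply(profiles, function(p) eventPsi(p)[names(evGene)])),
                ncol = length(profiles), dimnames = list(names(evGene), labs))
  mixRow <- function(w) {
    tot <- as.numeric(g %*% w[labs])
    ifelse(tot > 0, as.numeric((g * psi) %*% w[labs]) / tot, NA_real_)
  }
  pc <- mixRow(wCtrl); pt <- mixRow(wTreat)
  data.frame(event_id = names(evGene), gene_id = unname(evGene),
             psi_ctrl = pc, psi_treat = pt, delta_psi = pt - pc,
             psi_diff_celltype = psi[, 2] - psi[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected slope and correlation of the composition-shift relationship
#'
#' Regresses the noise-free predicted condition delta-PSI on the cell-type
#' PSI difference across events.  When expression weights are equal across
#' cell types, the mixture PSI is linear in the weights, so the slope equals
#' the astrocyte-weight change exactly and r = 1; heterogeneous expression
#' attenuates each event differently, pulling r below 1.  This explains why
#' a partial composition shift produces a regression slope strictly between
#' 0 and 1 against the full cell-type difference.
#'
#' @inheritParams predictMixtureDeltaPsi
#' @return list: `slope`, `r`, `n`, plus the per-event `table`; both NA,
#'   with a `degenerate` flag, when the events carry no spread in the
#'   cell-type difference.
#' @export
compositionShiftRegression <- function(profiles, wCtrl, wTreat) {
  tab <- predictMixtureDeltaPsi(profiles, wCtrl, wTreat)
  ok <- !is.na(tab$delta_psi)
  x <- tab$psi_diff_celltype[ok]; y <- tab$delta_psi[ok]
  if (length(x) < 2 || stats::sd(x) == 0)
    return(list(slope = NA_real_, r = NA_real_, n = sum(ok),
                degenerate = TRUE, table = tab))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)["x"]),
       r = if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y),
       n = sum(ok), degenerate = FALSE, table = tab)
}
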