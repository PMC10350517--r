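#' Convert an isoform ratio to an inclusion fraction and back
#'
#' With R the ratio of inclusion-form to skipping-form transcripts
#' (e.g. the SS4+/SS4- ratio of Nrxn1), the inclusion fraction is
#' \eqn{\psi = R / (1 + R)}; the inverse is \eqn{R = \psi / (1 - \psi)}.
#'
#' @param R positive isoform ratio(s).
#' @param psi inclusion fraction(s) in [0, 1).
#' @return `psiFromRatio` returns psi; `ratioFromPsi` returns R.
#' @examples
#' psiFromRatio(0.28)   # neuronal Nrxn1 SS4: 0.21875
#' psiFromRatio(36)     # astrocytic Nrxn1 SS4: 0.97297...
#' @export
psiFromRatio <- function(R) {
  stopifnot(all(R >= 0))
  R / (1 + R)
}

#' @rdname psiFromRatio
#' @export
ratioFromPsi <- function(psi) {
  stopifnot(all(psi >= 0 & psi < 1))
  psi / (1 - psi)
}

#' Mixture PSI of an event in a multi-component mRNA pool
#'
#' When mRNA from several cell types is pooled, each type contributes
#' transcripts of an event's gene in proportion to (mass weight w) x
#' (expression g), of which a fraction psi carry the included exon.  The
#' pooled inclusion fraction is therefore the expression-weighted mean
#' \deqn{\psi_{mix} = \sum_t w_t g_t \psi_t / \sum_t w_t g_t.}
#'
#' @param w numeric vector of mRNA-mass weights (>= 0, not all zero unless
#'   `g` is zero too).
#' @param g numeric vector of per-type expression of the event's gene.
#' @param psi numeric vector of per-type inclusion fractions in [0, 1].
#' @return mixture inclusion fraction; `NaN` when the pooled gene
#'   expression is zero.
#' @examples
#' mixturePsi(c(0.85, 0.15), c(2, 1), psiFromRatio(c(0.28, 36)))  # 0.28
#' @export
mixturePsi <- function(w, g, psi) {
  stopifnot(length(w) == length(g), length(g) == length(psi),
            all(w >= 0), all(g >= 0), all(psi >= 0 & psi <= 1))
  tot <- sum(w * g)
  if (tot == 0) return(NaN)
  sum(w * g * psi) / tot
}

#' Convert cell counts and per-cell RNA yields to mRNA-mass weights
#'
#' The mixture model weighs cell types by their share of total mRNA mass.
#' Given cell counts and an RNA yield per cell for each type, the weight of
#' type t is counts_t * yield_t normalised to sum to 1.
#'
#' @param counts named numeric vector of cell counts (>= 0).
#' @param yieldPerCell named numeric vector of relative RNA yield per cell,
#'   matched to `counts` (default: equal yields).
#' @return named numeric weight vector summing to 1.
#' @examples
#' cellCountsToWeights(c(neuron = 85, astrocyte = 15))
#' @export
cellCountsToWeights <- function(counts,
                                yieldPerCell = rep(1, length(counts))) {
  stopifnot(all(counts >= 0), all(yieldPerCell > 0), sum(counts) > 0)
  mass <- counts * rep_len(yieldPerCell, length(counts))
  mass / sum(mass)
}

# Deterministic per-sample substream seed from (seed, condition, replicate).
# 31-adic rolling hash mod a prime < 2^31; exact in double arithmetic.
sampleSeed <- function(seed, condition, replicate) {
  m <- 2147483563
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(paste0(condition, "#", replicate)))
    h <- (h * 31 + b) %% m
  as.integer(h)
}

stopIf <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)
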