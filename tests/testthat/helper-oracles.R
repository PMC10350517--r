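suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed forms are re-derived from first
# principles and likelihoods are maximised by brute-force grids.

# Mixture PSI by explicit transcript bookkeeping: each cell type contributes
# w * g transcripts of the event's gene, split into inclusion and skipping
# isoform pools; the pooled PSI is the inclusion pool's share.
bruteForceMixturePsi <- function(w, g, psi) {
  incPool <- 0
  skipPool <- 0
  for (t in seq_along(w)) {
    transcripts <- w[t] * g[t]
    incPool <- incPool + transcripts * psi[t]
    skipPool <- skipPool + transcripts * (1 - psi[t])
  }
  incPool / (incPool + skipPool)
}

# Binomial log-likelihood of pooled junction counts at inclusion fraction
# psi (independent re-derivation of the read-level model).
oracleLogLik <- function(psi, I, S, lI, lS) {
  th <- psi * lI / (psi * lI + (1 - psi) * lS)
  out <- numeric(length(psi))
  if (I > 0) out <- out + I * log(th)
  if (S > 0) out <- out + S * log1p(-th)
  out
}

# Constrained-LRT statistic by brute-force grid over the null boundary
# |psi1 - psi2| = c (both signs) plus the interior check.
gridLRT <- function(I1, S1, I2, S2, lI, lS, c, step = 2e-6) {
  psiHat <- function(I, S) (I / lI) / (I / lI + S / lS)
  p1 <- psiHat(I1, S1); p2 <- psiHat(I2, S2)
  if (abs(p1 - p2) <= c) return(0)
  llFree <- oracleLogLik(p1, I1, S1, lI, lS) +
    oracleLogLik(p2, I2, S2, lI, lS)
  best <- -Inf
  for (s in c(1, -1)) {
    lo <- max(0, -s * c); hi <- min(1, 1 - s * c)
    grid <- seq(lo, hi, by = step)
    ll <- oracleLogLik(grid, I1, S1, lI, lS) +
      oracleLogLik(grid + s * c, I2, S2, lI, lS)
    best <- max(best, max(ll))
  }
  max(2 * (llFree - best), 0)
}

# Direct-formula one-way ANOVA.
oracleAnova <- function(groups) {
  y <- unlist(groups)
  k <- length(groups); N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df = c(k - 1, N - k),
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

# Direct-formula paired t.
oraclePairedT <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE))
}

# Direct-formula Pearson r, t-transform p and Fisher-z CI.
oraclePearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  z <- 0.5 * log((1 + r) / (1 - r))
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(r = r, p = 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE),
       ci95 = (exp(2 * c(z - hw, z + hw)) - 1) / (exp(2 * c(z - hw, z + hw)) + 1))
}

# Direct-formula OLS slope of y on x.
oracleSlope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Expression matrices for the two profiles (exact replicate-free tables),
# convenient for marker curation against planted truth.
profileExprMatrix <- function(profile, label = cellType(profile)) {
  matrix(geneExpr(profile),
         dimnames = list(names(geneExpr(profile)), label))
}

# A minimal MarkerSet built directly (bypassing curation) for toy tests.
toyMarkerSet <- function(genes, types, minFpkm = 10, minFold = 10) {
  n <- length(genes)
  new("MarkerSet",
      table = data.frame(gene_id = genes, cell_type = types,
                         mean_high = rep(NA_real_, n),
                         mean_low = rep(NA_real_, n),
                         fold = rep(NA_real_, n)),
      criteria = list(minFpkm = minFpkm, minFold = minFold),
      provenance = "toy")
}
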