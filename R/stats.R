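#' One-way ANOVA
#'
#' Classic fixed-effects one-way analysis of variance:
#' F = MS_between / MS_within with df (k - 1, N - k) and a two-sided p from
#' the F distribution (equal variances assumed, as in the standard
#' figure-legend ANOVA).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list: `F`, `df` (length 2), `p`; when both between- and
#'   within-group variance are zero the statistic is undefined and returned
#'   as NA with a `degenerate` flag.
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))   # F = 3, df (2, 6)
#' @export
oneWayAnova <- function(groups) {
  stopIf(length(groups) < 2, "need at least 2 groups")
  stopIf(any(vapply(groups, length, integer(1)) < 2),
         "each group needs at least 2 values")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(y) == 0)
    return(list(F = NA_real_, df = c(length(groups) - 1L,
                                     length(y) - length(groups)),
                p = NA_real_, degenerate = TRUE))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, degenerate = FALSE)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero spread.
#' @param conf confidence level (default 0.95).
#' @return list: `statistic` (r), `df` (n - 2), `p` (two-sided, via the t
#'   transform), `ci95` (Fisher-z interval; at |r| = 1 the interval
#'   degenerates to r).
#' @examples
#' pearsonCI(c(1, 2, 3), c(1, 2, 4))   # r = 0.9820
#' @export
pearsonCI <- function(x, y, conf = 0.95) {
  stopIf(length(x) != length(y), "x and y must have equal length")
  stopIf(length(x) < 3, "need at least 3 observations")
  stopIf(stats::sd(x) == 0 || stats::sd(y) == 0,
         "constant vector: correlation undefined")
  n <- length(x)
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15)
    return(list(statistic = r, df = n - 2L, p = 0, ci95 = c(r, r)))
  ht <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(statistic = r, df = n - 2L, p = ht$p.value,
       ci95 = tanh(c(z - q * se, z + q * se)))
}
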