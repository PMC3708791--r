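# Shared two-sample statistics: the Mann-Whitney-Wilcoxon rank-sum test
# used by both the volatile-quantification and immunity modules, and
# significance-star annotation.

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' The statistic is the sum of (mid)ranks of `x` in the pooled sample.
#' For combined n <= `exact_limit` the null distribution of the rank sum
#' is computed exactly over all equally likely assignments of the pooled
#' ranks to the two groups (ties handled by midranks), by counting
#' subsets of each size and rank total; otherwise the normal
#' approximation with tie-corrected variance is used (no continuity
#' correction). The two-sided p-value is `2 * min(P(W <= w), P(W >= w))`
#' capped at 1, so identical groups give exactly 1.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_limit largest combined sample size for the exact null
#'   (default 12).
#' @return list with `statistic` (rank sum of `x`), `p.value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y, exact_limit = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (N <= exact_limit) {
    p <- rank_sum_exact_p(r, n1, w)
    method <- "exact"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(statistic = w, p.value = p, method = method)
}

# Exact null of the rank sum via subset counting: dynamic programme over
# the doubled midranks (integers), counting subsets of size n1 by rank
# total. Returns the two-sided p for observed rank sum w.
rank_sum_exact_p <- function(r, n1, w) {
  r2 <- as.integer(round(2 * r))
  smax <- sum(r2)
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  counts[1L, 1L] <- 1
  for (v in r2) {
    kmax <- n1
    for (k in seq(kmax, 1L)) {
      shifted <- c(rep(0, v), counts[k, seq_len(smax + 1L - v)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  dist <- counts[n1 + 1L, ]
  total <- sum(dist)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(dist[seq_len(w2 + 1L)]) / total
  p_ge <- sum(dist[(w2 + 1L):(smax + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise
#' an empty string (vectorised).
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}
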