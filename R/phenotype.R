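# RNAi phenotype-strength scoring: per-beetle chemical changes relative
# to control means are condensed into a six-level strength scale.
#
# Strength scale (smaller number = stronger effect):
#   1  very strong: at least one component undetectable or <= 5% of the
#      control left, in every injected beetle
#   2  strong: at least one component reduced by 75-95% or increased by
#      more than 75%, in every injected beetle
#   3  strong/very strong but only in a subset of the injected beetles
#   4  some changes: at least one component 25-75% reduced or increased
#      in the majority of beetles
#   5  neglectable: every change below 25%
#   6  uncloned or untested
# Evidence from the thoracic or the abdominal glands counts equally.

#' Signed relative change of a component against its control mean
#'
#' `(kd - control) / control`: -1 means undetectable, -0.8 an 80%
#' reduction, +1 a doubling.
#'
#' @param kd_amount knock-down amount(s).
#' @param control_mean positive control mean(s).
#' @return signed relative change (vectorised).
#' @export
component_change <- function(kd_amount, control_mean) {
  if (any(!is.finite(control_mean)) || any(control_mean <= 0))
    stop("control_mean must be finite and > 0")
  (kd_amount - control_mean) / control_mean
}

#' Classify the phenotype strength of one knock-down gene
#'
#' Takes per-beetle signed relative changes (see [component_change]) of
#' each gland component and assigns a strength 1-5; untested genes are
#' class 6. Per beetle, across both glands and all components:
#' class-1 evidence is any component at or below 5% of the control
#' (change <= -0.95), class-2 evidence any component reduced by at least
#' 75% or increased by at least 75%. If class-1 evidence holds in every
#' beetle the gene is strength 1; if strong (class-1 or class-2)
#' evidence holds in every beetle, strength 2; if it holds in at least
#' `min_penetrance` beetles but not all, strength 3. Otherwise, if some
#' component shows a moderate change (25-75%) in at least a `majority`
#' fraction of beetles, strength 4; else 5.
#'
#' @param changes data.frame with columns `beetle`, `gland`, `compound`,
#'   `change` (signed relative change), or `NULL`/empty with
#'   `tested = FALSE`.
#' @param tested logical; untested or uncloned genes return 6.
#' @param min_penetrance minimum number of beetles with strong evidence
#'   for class 3 (default 1).
#' @param majority fraction of beetles required for class-4 evidence
#'   (default 0.5).
#' @return integer strength 1-6.
#' @export
classify_strength <- function(changes, tested = TRUE,
                              min_penetrance = 1, majority = 0.5) {
  if (!tested) return(6L)
  if (is.null(changes) || nrow(changes) == 0L)
    stop("tested gene needs at least one beetle measurement")
  stopifnot(all(c("beetle", "compound", "change") %in% names(changes)))
  if (!"gland" %in% names(changes)) changes$gland <- "both"
  if (any(changes$change < -1))
    stop("relative change below -1 is impossible (negative amount)")
  beetles <- unique(changes$beetle)
  nb <- length(beetles)
  per_beetle <- function(pred)
    vapply(beetles, function(b) any(pred(changes$change[changes$beetle == b])),
           logical(1))
  class1 <- per_beetle(function(d) d <= -0.95)
  strong <- per_beetle(function(d) d <= -0.75 | d >= 0.75)
  if (all(class1)) return(1L)
  if (all(strong)) return(2L)
  if (sum(strong) >= min_penetrance && sum(strong) > 0) return(3L)
  # class 4: one component (in either gland) moderately changed in the
  # majority of beetles
  moderate <- abs(changes$change) >= 0.25 & abs(changes$change) < 0.75
  keys <- interaction(changes$gland, changes$compound, drop = TRUE)
  for (k in levels(keys)) {
    sel <- keys == k & moderate
    if (length(unique(changes$beetle[sel])) >= majority * nb &&
        any(sel))
      return(4L)
  }
  5L
}

#' Summarise phenotype strengths over a knock-down cohort
#'
#' Tabulates strengths 1-6 plus the headline fractions: strong effects
#' (strengths 1-3) and any chemical alteration (strengths 1-4), as
#' percentages of the tested genes.
#'
#' @param strengths integer vector of strengths (1-6), one per gene.
#' @return list with `counts` (named table over 1-6), `n_tested`,
#'   `strong_n`, `strong_pct`, `altered_n`, `altered_pct`.
#' @export
cohort_summary <- function(strengths) {
  counts <- vapply(1:6, function(s) sum(strengths == s), integer(1))
  names(counts) <- as.character(1:6)
  n_tested <- sum(counts[1:5])
  strong <- sum(counts[1:3])
  altered <- sum(counts[1:4])
  list(counts = counts,
       n_tested = n_tested,
       strong_n = strong,
       strong_pct = if (n_tested > 0) 100 * strong / n_tested else 0,
       altered_n = altered,
       altered_pct = if (n_tested > 0) 100 * altered / n_tested else 0)
}
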