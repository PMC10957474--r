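#' Two-sample test of equal proportions
#'
#' Yates-continuity-corrected chi-squared test comparing `x2/n2` against
#' `x1/n1`, with a Wald confidence interval for the difference that includes
#' the matching continuity term. The orientation is explicit:
#' `delta = x2/n2 - x1/n1` (second group minus first), so callers control the
#' printed sign. Delegates to [stats::prop.test()].
#'
#' @param x1,n1 Successes and total in the first (reference) group.
#' @param x2,n2 Successes and total in the second group.
#' @param conf Confidence level (default 0.95).
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `delta`, `ci` (length 2), `chi2`, `p`, and the group
#'   proportions `p1`, `p2`.
#' @export
prop_test <- function(x1, n1, x2, n2, conf = 0.95, correct = TRUE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  if ((x1 + x2) == 0 || (x1 + x2) == (n1 + n2)) {
    stop("degenerate 2x2 table: a margin is zero")
  }
  # prop.test estimates (first - second); pass group 2 first so the
  # reported difference is p2 - p1
  ht <- suppressWarnings(
    stats::prop.test(c(x2, x1), c(n2, n1), conf.level = conf,
                     correct = correct))
  list(delta = unname(ht$estimate[1] - ht$estimate[2]),
       ci = as.vector(ht$conf.int),
       chi2 = unname(ht$statistic),
       p = ht$p.value,
       p1 = x1 / n1, p2 = x2 / n2)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' that of the observed table. Delegates to [stats::fisher.test()].
#'
#' @param tab 2x2 integer matrix of counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  stats::fisher.test(tab)$p.value
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p-value when the combined sample is small (`n <= 12`)
#' with no ties; otherwise the normal approximation with tie and continuity
#' corrections. Delegates to [stats::wilcox.test()].
#'
#' @param a,b Numeric samples.
#' @return List with the rank-sum statistic `W` and the two-sided `p`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (length(a) + length(b)) <= 12 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value, exact = use_exact)
}
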