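#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test of independence in a 2x2 contingency table, using the
#' point-probability definition of the two-sided p-value: the sum of
#' hypergeometric probabilities (margins fixed) of all tables whose point
#' probability does not exceed that of the observed table, compared with a
#' relative tolerance of 1e-7 so that boundary tables are classified
#' deterministically across platforms.
#'
#' The reported odds ratio is the sample cross-product ratio `(a*d)/(b*c)`:
#' `Inf` when `b*c == 0` and `a*d > 0`, and `NA` (undefined) when both
#' products are zero.  This differs from the conditional maximum-likelihood
#' estimate printed by [stats::fisher.test()].
#'
#' @param a,b,c,d Non-negative integer counts, row-wise: the table is
#'   `rbind(c(a, b), c(c, d))`.  Alternatively `a` may be a 2x2 matrix.
#' @return A list of class `"mutdyn_test"` with elements `p_value`,
#'   `odds_ratio`, `statistic` (the observed count `a`), and `method`.
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)$p_value  # 0.4857143
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("contingency counts must be non-negative integers")
  if (sum(counts) == 0)
    stop("contingency table is empty")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  ad <- a * d; bc <- b * c
  or <- if (ad == 0 && bc == 0) NA_real_ else if (bc == 0) Inf else ad / bc
  structure(
    list(p_value = min(p, 1), odds_ratio = or, statistic = a,
         method = "Fisher's exact test (two-sided, point probability)"),
    class = "mutdyn_test"
  )
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` marked items when `n` items are drawn without replacement from
#' a universe of `N` items of which `K` are marked.  Computed in log space via
#' [stats::phyper()] for numerical stability; this is the enrichment p-value
#' used throughout the package.
#'
#' @param k Observed overlap (number of marked items drawn).
#' @param K Number of marked items in the universe (gene-set size).
#' @param n Number of items drawn (query size).
#' @param N Universe size.
#' @return A probability in (0, 1].
#' @examples
#' hypergeometric_upper_tail(5, 5, 5, 10)  # 1/choose(10, 5)
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  v <- c(k, K, n, N)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("hypergeometric arguments must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric counts: need 0 <= k <= min(K, n) <= N")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR q-values, returned in the input order.  Thin validated wrapper
#' over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`s are propagated.
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact two-sided p-value by enumeration of rank assignments when the smaller
#' group has at most `exact_threshold` observations and there are no ties;
#' otherwise the mid-rank normal approximation with continuity correction.
#' The default threshold keeps cohorts of the size this package targets
#' (tens of samples) on the exact path.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_threshold Largest smaller-group size for which the exact
#'   distribution is enumerated (default 25).
#' @return A list of class `"mutdyn_test"` with `p_value`, `statistic` (the
#'   rank-sum statistic W), `exact` flag, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 25L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= exact_threshold
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  p <- ht$p.value
  if (is.na(p)) p <- 1  # degenerate: zero-variance rank configuration
  structure(
    list(p_value = min(p, 1), statistic = unname(ht$statistic), exact = exact,
         method = "Wilcoxon rank-sum test (two-sided)"),
    class = "mutdyn_test"
  )
}

#' Wilcoxon signed-rank test for paired samples (two-sided)
#'
#' Pairs with zero difference are dropped before ranking.  The p-value is
#' exact (enumeration over sign patterns) when at most `exact_threshold`
#' non-zero differences remain and their magnitudes are untied; otherwise the
#' normal approximation with continuity correction is used.  With no non-zero
#' differences the test is vacuous and `p_value = 1` with `n_effective = 0`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_threshold Largest effective n for the exact path (default 15).
#' @return A list of class `"mutdyn_test"` with `p_value`, `statistic` (V),
#'   `n_effective`, `exact` flag, and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_threshold = 15L) {
  if (length(x) != length(y))
    stop("paired vectors must have equal length")
  keep <- !(is.na(x) | is.na(y))
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n_eff <- length(d)
  if (n_eff == 0) {
    return(structure(
      list(p_value = 1, statistic = NA_real_, n_effective = 0L, exact = TRUE,
           method = "Wilcoxon signed-rank test (two-sided)"),
      class = "mutdyn_test"
    ))
  }
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && n_eff <= exact_threshold
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE)
  )
  p <- ht$p.value
  if (is.na(p)) p <- 1
  structure(
    list(p_value = min(p, 1), statistic = unname(ht$statistic),
         n_effective = n_eff, exact = exact,
         method = "Wilcoxon signed-rank test (two-sided)"),
    class = "mutdyn_test"
  )
}

#' @export
print.mutdyn_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$statistic) && !is.na(x$statistic))
    cat("  statistic =", format(x$statistic), "\n")
  if (!is.null(x$odds_ratio))
    cat("  odds ratio =", format(x$odds_ratio), "\n")
  cat("  p-value =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}
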