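#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass definition of the two-sided test: the p-value is the sum
#' of hypergeometric probabilities, over all tables with the same margins, of
#' tables whose probability does not exceed that of the observed table (up to
#' a small relative tolerance on the comparison). This matches the convention
#' of mainstream implementations and reproduces published worked examples for
#' trunk-versus-branch driver clonality contrasts.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are the two groups,
#'   columns the two outcomes, i.e. the table is \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' fisher_exact_two_sided(2, 10, 9, 3)   # 0.0123 to 4 dp
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (length(counts) != 4L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("contingency table must hold four non-negative integer counts")
  }
  if (sum(counts) == 0L) {
    stop("all-zero contingency table: Fisher exact test undefined")
  }
  stats::fisher.test(matrix(counts, nrow = 2L, byrow = TRUE))$p.value
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact null distribution when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie correction
#' (no continuity correction, so the two regimes agree closely near the
#' switchover).
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @return List with elements \code{U} (statistic for \code{x}, i.e. the
#'   number of (x, y) pairs with x > y counting ties as 1/2) and
#'   \code{p_value} (two-sided).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 20L) && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y,
    alternative = "two.sided",
    exact = use_exact, correct = FALSE
  ))
  list(U = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Constant input has no defined rank
#' correlation; controlled by \code{on_constant}.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param on_constant Either \code{"error"} (default) or \code{"na"}: what to
#'   do when either input is constant.
#' @return rho in \[-1, 1\] (or NA if \code{on_constant = "na"}).
#' @export
spearman_rho <- function(x, y, on_constant = c("error", "na")) {
  on_constant <- match.arg(on_constant)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (on_constant == "error") stop("constant input: Spearman rho undefined")
    warning("constant input: Spearman rho undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Hypergeometric point mass
#'
#' Probability of drawing \code{k} white balls in \code{n} draws without
#' replacement from an urn with \code{m} white and \code{nb} black balls.
#' Thin wrapper kept for use by enumeration-style checks.
#'
#' @param k Number of white balls drawn.
#' @param m,nb Numbers of white and black balls in the urn.
#' @param n Number of draws.
#' @return Probability mass.
#' @export
hypergeom_mass <- function(k, m, nb, n) {
  stats::dhyper(k, m, nb, n)
}
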