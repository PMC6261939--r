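#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact enumeration when both samples have at most `exact_max` observations
#' and the pooled data are tie-free; otherwise the normal approximation with
#' tie and continuity correction. The statistic reported is the
#' Mann-Whitney U of `x` versus `y`. Identical multisets give p = 1 (a
#' degenerate comparison, not an error).
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param exact_max Largest per-group size for which the exact distribution
#'   is used (tie-free data only).
#'
#' @return A one-row `test_result` tibble: `statistic`, `p_value`, `method`,
#'   `n1`, `n2`.
#' @export
wmw_test <- function(x, y, exact_max = 10) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  p <- unname(wt$p.value)
  if (ties && length(unique(c(x, y))) == 1) p <- 1  # fully degenerate
  tibble::tibble(statistic = unname(wt$statistic), p_value = min(p, 1),
                 method = if (exact) "wmw_exact" else "wmw_normal_approx",
                 n1 = length(x), n2 = length(y))
}

#' Pearson correlation test
#'
#' Correlation coefficient with the two-sided p-value from the t-transform
#' on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#'
#' @return A one-row `test_result` tibble (`statistic` is r).
#' @export
pearson_cor_test <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(statistic = unname(ct$estimate), p_value = ct$p.value,
                 method = "pearson", n1 = length(x), n2 = length(y))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, monotone, clipped to `[0, 1]`,
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values.
#'
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' ROC area under the curve
#'
#' `AUC = (concordant pairs + 0.5 * tied pairs) / (n1 * n2)` over all
#' positive-negative pairs, computed by the rank formula; ties get half
#' credit (the trapezoidal convention). Higher scores are taken to predict
#' the positive class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1/TRUE = positive class, e.g. resistant).
#'
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("lengths differ", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks give half credit for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
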