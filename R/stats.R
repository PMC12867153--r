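#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Wraps [stats::wilcox.test()] with the conventions used throughout the
#' package: exact enumeration when the smaller group has at most 10
#' observations and there are no ties, otherwise the mid-rank normal
#' approximation with continuity correction. Two samples that are
#' completely identical in value carry no ordering information; they
#' return `p = 1` with a flag instead of an ill-defined test.
#'
#' @param a,b Nonempty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List: `statistic` (the Mann-Whitney U of `a` vs `b`),
#'   `p_value`, `method`, and `degenerate` (all-identical flag).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 1, length(b) >= 1,
            is.numeric(a), is.numeric(b), !anyNA(a), !anyNA(b))
  if (length(unique(c(a, b))) == 1L) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(mode,
                  auto = min(length(a), length(b)) <= 10L && !ties,
                  exact = TRUE,
                  normal = FALSE)
  if (exact && ties) stop("exact mode is unavailable with ties")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal", degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with enforced monotonicity, capped at 1;
#' input order is preserved.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' ROC curve and AUC by the rank formulation
#'
#' The AUC is computed by the Mann-Whitney identity
#' `AUC = (sum of positive-case ranks - n1 (n1 + 1) / 2) / (n1 n0)`,
#' with mid-ranks handling ties (ties contribute 1/2). The full curve
#' sweeps every distinct score as a `>= threshold` decision rule.
#'
#' @param scores Numeric predictor values (higher = more positive).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return Object of class `"roc_result"`: `thresholds`,
#'   `sensitivities`, `specificities` (one entry per cut, from the
#'   all-positive to the all-negative rule) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # mid-ranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & !labels) / n0, numeric(1))
  structure(list(thresholds = thr, sensitivities = sens,
                 specificities = spec, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificities, x$sensitivities, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
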