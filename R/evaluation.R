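# Scoring DE results against ground truth: confusion counts, MCC, type-1
# error, ROC curves, sensitivity at fixed FPR.

truth_flags <- function(truth) {
  if (is.data.frame(truth)) truth$is_de else as.logical(truth)
}

#' Confusion counts at a p-value threshold
#'
#' A gene is called positive iff its p-value is `<= alpha` (boundary
#' inclusive). Genes with missing p-values are excluded from the counts and
#' reported in `n_missing`.
#'
#' @param p_values Per-gene p-values (may contain `NA`).
#' @param truth Logical DE flags, or a truth data frame with an `is_de`
#'   column, of the same length.
#' @param alpha Threshold in (0, 1).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`, `alpha`, `n_missing`.
#' @export
confusion_at_alpha <- function(p_values, truth, alpha = 0.05) {
  is_de <- truth_flags(truth)
  if (length(p_values) != length(is_de))
    stop("p_values and truth have different lengths", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  ok <- !is.na(p_values)
  call_pos <- p_values[ok] <= alpha
  de <- is_de[ok]
  structure(list(
    tp = sum(call_pos & de),
    fp = sum(call_pos & !de),
    tn = sum(!call_pos & !de),
    fn = sum(!call_pos & de),
    alpha = alpha,
    n_missing = sum(!ok)
  ), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \eqn{(tp \cdot tn - fp \cdot fn) / \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},
#' a balanced summary of a binary confusion matrix in \[-1, 1\]: 1 for a
#' perfect classifier, 0 at chance, -1 for perfect disagreement. When any
#' factor of the denominator is zero the score is 0 by convention.
#'
#' @param counts A `confusion_counts` object (or any list with tp/fp/tn/fn).
#' @return A number in \[-1, 1\].
#' @examples
#' mcc(confusion_at_alpha(c(0.01, 0.9, 0.02, 0.8), c(TRUE, FALSE, TRUE, FALSE)))
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Empirical type-1 error over null genes
#'
#' The fraction of truly non-DE genes called significant at `alpha`:
#' fp / (fp + tn). Intended for null-only p-value vectors; missing p-values
#' are excluded.
#'
#' @param p_values P-values of null genes.
#' @param alpha Threshold in (0, 1).
#' @return Proportion in \[0, 1\].
#' @export
type1_error <- function(p_values, alpha = 0.05) {
  cc <- confusion_at_alpha(p_values, rep(FALSE, length(p_values)), alpha)
  cc$fp / (cc$fp + cc$tn)
}

#' ROC curve of p-values against ground truth
#'
#' Sweeps the decision threshold over the unique observed p-values (tied
#' p-values share one threshold point — an honest step curve for discrete
#' p-value distributions), anchors the curve at (0,0) and (1,1), and computes
#' the area under the curve by the trapezoid rule. Missing p-values are
#' excluded.
#'
#' @param p_values Per-gene p-values.
#' @param truth Logical DE flags or a truth data frame (`is_de` column).
#' @return An object of class `roc_curve` with fields `fpr`, `tpr` (each
#'   non-decreasing, from 0 to 1) and `auc`.
#' @export
roc_curve <- function(p_values, truth) {
  is_de <- truth_flags(truth)
  if (length(p_values) != length(is_de))
    stop("p_values and truth have different lengths", call. = FALSE)
  ok <- !is.na(p_values)
  p <- p_values[ok]; d <- is_de[ok]
  n_pos <- sum(d); n_neg <- sum(!d)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one DE and one null gene with non-missing p",
         call. = FALSE)
  o <- order(p)
  p <- p[o]; d <- d[o]
  last <- !duplicated(p, fromLast = TRUE)   # last index of each tie block
  tpr <- c(0, cumsum(d)[last] / n_pos)
  fpr <- c(0, cumsum(!d)[last] / n_neg)
  # the final threshold (largest p) always reaches (1, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Sensitivity at a fixed false-positive rate
#'
#' Reads the true-positive rate off a ROC curve at `target_fpr` by linear
#' interpolation between the bracketing curve points (taking the upper
#' envelope at tied FPR values), the reproducible analogue of reading a value
#' off a plotted curve.
#'
#' @param curve A `roc_curve`.
#' @param target_fpr Target false-positive rate in (0, 1).
#' @return Sensitivity (TPR) in \[0, 1\].
#' @examples
#' cv <- structure(list(fpr = c(0, 0.1, 1), tpr = c(0, 0.8, 1), auc = NA),
#'                 class = "roc_curve")
#' sensitivity_at_fpr(cv, 0.05)  # 0.4
#' @export
sensitivity_at_fpr <- function(curve, target_fpr) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!is.numeric(target_fpr) || length(target_fpr) != 1L ||
      target_fpr <= 0 || target_fpr >= 1)
    stop("target_fpr must lie in (0, 1)", call. = FALSE)
  out <- stats::approx(curve$fpr, curve$tpr, xout = target_fpr,
                       ties = max, rule = 2)$y
  min(max(out, 0), 1)
}

# One row of benchmark metrics for a de_result against truth.
evaluate_result <- function(res, truth, alpha = 0.05) {
  is_de <- truth_flags(truth)
  cc <- confusion_at_alpha(res$p_values, is_de, alpha)
  null_p <- res$p_values[!is_de]
  list(
    mcc = mcc(cc),
    type1 = if ((cc$fp + cc$tn) > 0) cc$fp / (cc$fp + cc$tn) else NA_real_,
    sensitivity = if ((cc$tp + cc$fn) > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
    n_failed = res$n_failed
  )
}
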