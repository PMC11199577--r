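#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return fraction of correct predictions.
#' @export
accuracy <- function(pred, truth) {
  if (!length(truth)) stop("empty input")
  if (length(pred) != length(truth)) stop("length(pred) != length(truth)")
  mean(as.character(pred) == as.character(truth))
}

#' Majority-class (naive) baseline accuracy
#'
#' The accuracy of a degenerate classifier that always predicts the most
#' frequent class.
#'
#' @param truth label vector.
#' @return largest class frequency.
#' @export
majority_baseline <- function(truth) {
  if (!length(truth)) stop("empty input")
  max(table(truth)) / length(truth)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0 when
#' any factor of the denominator is 0 (e.g. an always-majority predictor).
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be non-negative")
  if (tp + tn + fp + fn <= 0) stop("empty confusion matrix")
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Confusion counts with "case" = the positive class.
confusion_counts <- function(pred, truth, positive) {
  p <- as.character(pred) == positive
  t <- as.character(truth) == positive
  c(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' ROC area under the curve
#'
#' Computed through the Mann-Whitney identity: the fraction of case/control
#' pairs whose decision values are correctly ordered, counting ties as 1/2.
#' Implemented with midranks, which is algebraically identical to the
#' pairwise count.
#'
#' @param scores decision values (larger = more case-like).
#' @param truth binary labels; the positive class is `positive`.
#' @param positive label of the positive class (default the second factor
#'   level, or `1` for 0/1 input).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, positive = NULL) {
  truth <- as_class_factor(truth)
  if (nlevels(truth) != 2) stop("both classes must be present")
  if (is.null(positive)) positive <- levels(truth)[2]
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The p-value is exact
#' (enumeration) when the smaller sample has at most 8 observations and
#' there are no ties; otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param a,b numeric vectors.
#' @return list with `U` (for `a` versus `b`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  # all-tied samples: the normal approximation degenerates (zero variance);
  # there is no evidence of a shift, so the two-sided p is 1
  if (is.na(p)) p <- 1
  list(U = unname(wt$statistic), p = p)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student t (default) or Welch t from per-group means, SDs
#' and sizes — the form needed to reproduce printed cohort-table p-values.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summaries; `n >= 2`, `sd >= 0`.
#' @param welch use the Welch (unequal-variance) variant.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  if (se2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means; p = 0")
    return(list(t = sign(mean1 - mean2) * Inf, df = df, p = 0))
  }
  t <- (mean1 - mean2) / sqrt(se2)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
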