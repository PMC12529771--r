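# Classification and regression metrics shared by the protonation and ADMET
# pipelines.  ROC-AUC uses the rank (Mann-Whitney) formulation with midranks
# for ties; PR-AUC is average precision (step-wise integral of the
# precision-recall curve).

#' Binary classification metrics
#'
#' Computes accuracy, precision, recall, F1, Cohen's kappa, Matthews
#' correlation coefficient, ROC-AUC, PR-AUC and the confusion matrix.
#' Thresholded metrics use `threshold`; the AUCs are threshold-free.  With a
#' one-class label vector the AUCs are `NA` and the remaining metrics are
#' still computed.
#'
#' @param labels 0/1 vector of true classes.
#' @param probs predicted probabilities (or scores for the AUCs).
#' @param threshold decision threshold for the thresholded metrics.
#' @return list of metrics plus `confusion` (2x2 matrix: rows = truth,
#'   columns = prediction).
#' @export
classification_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs),
            all(labels %in% c(0, 1)), threshold > 0, threshold < 1)
  labels <- as.integer(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(labels == 1 & pred == 1)
  tn <- sum(labels == 0 & pred == 0)
  fp <- sum(labels == 0 & pred == 1)
  fn <- sum(labels == 1 & pred == 0)
  n <- length(labels)
  accuracy <- (tp + tn) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  # Cohen's kappa: observed vs chance agreement
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_
  both <- length(unique(labels)) == 2L
  list(accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
       kappa = kappa, mcc = mcc,
       roc_auc = if (both) roc_auc(probs, labels) else NA_real_,
       pr_auc = if (both) pr_auc(probs, labels) else NA_real_,
       confusion = matrix(c(tn, fn, fp, tp), 2, 2,
                          dimnames = list(truth = c("0", "1"),
                                          predicted = c("0", "1"))))
}

#' ROC-AUC by the Mann-Whitney rank statistic
#'
#' Equals the probability that a random positive scores above a random
#' negative, counting ties as one half (midranks).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 true classes (both must be present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("ROC-AUC needs both classes present")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC (average precision)
#'
#' Step-wise integral of precision over recall: sum of precision at each
#' positive hit times the recall increment, scanning scores in descending
#' order (ties grouped).
#'
#' @inheritParams roc_auc
#' @return average precision in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("PR-AUC needs both classes present")
  # group tied scores so the curve is threshold-based
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tabulate(grp)
  tp <- cumsum(tp_g)
  fp <- cumsum(n_g - tp_g)
  precision <- tp / (tp + fp)
  recall <- tp / n1
  drecall <- diff(c(0, recall))
  sum(precision * drecall)
}

#' Regression metrics: Pearson correlation and mean absolute error
#'
#' @param actual,predicted numeric vectors.
#' @return list with `pearson_r` and `mae`.
#' @export
regression_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  list(pearson_r = cor(actual, predicted), mae = mean(abs(actual - predicted)))
}
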