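# Evaluation metrics: 3x3 confusion matrix, accuracy, per-class
# precision/recall/F1, macro- and weighted-F1, one-vs-rest AUC with midrank
# tie handling, macro-AUC.

#' Confusion matrix for three risk classes
#'
#' Rows are true classes, columns predicted classes, both ordered
#' low/medium/high.
#'
#' @param y_true,y_pred Integer label vectors in {0,1,2}, equal length.
#' @return 3x3 integer matrix with dimnames `low/medium/high`.
#' @export
confusion_matrix3 <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, "y_true")
  y_pred <- check_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  cm <- table(factor(y_true, levels = 0:2), factor(y_pred, levels = 0:2))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(true = risk_levels(),
                               predicted = risk_levels()))
  cm
}

#' Classification report from labels
#'
#' Accuracy, per-class precision/recall/F1 (0/0 conventions: 0 with a
#' warning), macro-F1 (unweighted mean), weighted-F1 (weights `n_c / N`
#' from the true labels).
#'
#' @param y_true,y_pred Integer label vectors in {0,1,2}.
#' @return An object of class `metrics_report` (list; see
#'   [report_from_confusion()]).
#' @export
classification_report <- function(y_true, y_pred) {
  report_from_confusion(confusion_matrix3(y_true, y_pred))
}

#' Classification report from a 3x3 confusion matrix
#'
#' @param cm 3x3 count matrix, rows = true class, columns = predicted, in
#'   low/medium/high order.
#' @return A `metrics_report`: list with `accuracy`, `precision`, `recall`,
#'   `f1` (named per-class vectors), `macro_f1`, `weighted_f1`, `n_c`, `w_c`
#'   and the `confusion` matrix.
#' @export
report_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(3, 3)) || any(cm < 0))
    stop("cm must be a non-negative 3x3 matrix")
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  pred_c <- colSums(cm)
  true_c <- rowSums(cm)
  precision <- safe_div(tp, pred_c, "precision")
  recall <- safe_div(tp, true_c, "recall")
  f1 <- safe_div(2 * precision * recall, precision + recall, "F1")
  names(precision) <- names(recall) <- names(f1) <- risk_levels()
  w <- true_c / N
  structure(list(accuracy = sum(tp) / N,
                 precision = precision, recall = recall, f1 = f1,
                 macro_f1 = mean(f1),
                 weighted_f1 = sum(w * f1),
                 n_c = stats::setNames(as.integer(true_c), risk_levels()),
                 w_c = stats::setNames(w, risk_levels()),
                 confusion = cm),
            class = "metrics_report")
}

safe_div <- function(num, den, what) {
  zero <- den == 0
  if (any(zero))
    warning(what, " undefined (0/0) for class(es) ",
            paste(risk_levels()[zero], collapse = ", "), "; reported as 0")
  out <- numeric(length(num))
  out[!zero] <- num[!zero] / den[!zero]
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Classification report (N =", sum(x$n_c), ")\n")
  tab <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(tab, 4))
  cat(sprintf("accuracy %.4f | macro-F1 %.4f | weighted-F1 %.4f\n",
              x$accuracy, x$macro_f1, x$weighted_f1))
  invisible(x)
}

#' One-vs-rest ROC AUC per class and macro-AUC
#'
#' Per-class AUC equals the trapezoidal area under the one-vs-rest ROC with
#' midrank tie handling (the Mann-Whitney statistic); macro-AUC is their
#' unweighted mean.
#'
#' @param y_true Integer labels in {0,1,2}; every class needs at least one
#'   positive and one negative instance.
#' @param scores N x 3 score matrix, column c giving the score for class
#'   c - 1.
#' @return Named list with `auc` (per-class vector) and `macro_auc`.
#' @export
roc_auc_ovr <- function(y_true, scores) {
  y_true <- check_labels(y_true, "y_true")
  scores <- as.matrix(scores)
  if (ncol(scores) != 3 || nrow(scores) != length(y_true))
    stop("scores must be an N x 3 matrix aligned with y_true")
  auc <- numeric(3)
  for (cls in 0:2) {
    pos <- y_true == cls
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0)
      stop("class ", risk_levels()[cls + 1],
           " lacks positive or negative instances")
    r <- rank(scores[, cls + 1], ties.method = "average")
    auc[cls + 1] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  names(auc) <- risk_levels()
  list(auc = auc, macro_auc = mean(auc))
}
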