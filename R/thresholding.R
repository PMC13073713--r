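# Threshold study: sweep the high-risk threshold over a grid, compute
# per-class metrics at each point, select the minimal threshold attaining
# the maximal high-risk F1, and build one-vs-rest precision-recall curves.

#' Per-class metrics along a threshold grid
#'
#' For each grid threshold, labels are produced by [decide_labels()] and
#' per-class precision/recall/F1 computed.
#'
#' @param y_true Integer labels in {0,1,2}.
#' @param P_final N x 3 probability matrix.
#' @param grid Strictly increasing threshold grid (default 0.1..0.9 by 0.1).
#' @return data.frame of class `threshold_curve`: one row per threshold with
#'   columns `tau`, `precision_<class>`, `recall_<class>`, `f1_<class>` and
#'   `n_pred_high`.
#' @export
threshold_metric_curve <- function(y_true, P_final,
                                   grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(grid) == 0) stop("threshold grid must be non-empty")
  if (is.unsorted(grid, strictly = TRUE))
    stop("threshold grid must be strictly increasing")
  y_true <- check_labels(y_true, "y_true")
  rows <- lapply(grid, function(tau) {
    pred <- decide_labels(P_final, tau)
    rep_ <- suppressWarnings(classification_report(y_true, pred))
    out <- c(tau = tau, setNames(rep_$precision,
                                 paste0("precision_", risk_levels())),
             setNames(rep_$recall, paste0("recall_", risk_levels())),
             setNames(rep_$f1, paste0("f1_", risk_levels())),
             n_pred_high = sum(pred == 2L))
    as.data.frame(as.list(out))
  })
  curve <- do.call(rbind, rows)
  class(curve) <- c("threshold_curve", class(curve))
  curve
}

#' Select the optimal high-risk threshold
#'
#' The smallest grid threshold whose target-class F1 equals the grid
#' maximum (first attainment, no interpolation).
#'
#' @param curve A [threshold_metric_curve()] result.
#' @param target_class Class whose F1 is maximized (default `"high"`).
#' @return The selected threshold (scalar).
#' @export
select_optimal_threshold <- function(curve, target_class = "high") {
  if (nrow(curve) == 0) stop("empty threshold curve")
  col <- paste0("f1_", target_class)
  if (!col %in% names(curve)) stop("unknown target class: ", target_class)
  f1 <- curve[[col]]
  min(curve$tau[f1 >= max(f1) - 1e-12])  # order-independent first attainment
}

#' One-vs-rest precision-recall curve for one class
#'
#' Standard PR points at every distinct score cutoff (predict positive when
#' score >= cutoff), ordered by increasing cutoff so recall is
#' non-increasing along the curve.
#'
#' @param y_true Integer labels in {0,1,2}.
#' @param scores Numeric score vector for the target class.
#' @param class_c Target class (0, 1 or 2).
#' @return data.frame with columns `cutoff`, `recall`, `precision`.
#' @export
precision_recall_curve_ovr <- function(y_true, scores, class_c) {
  y_true <- check_labels(y_true, "y_true")
  if (length(scores) != length(y_true))
    stop("scores must align with y_true")
  pos <- y_true == class_c
  if (sum(pos) == 0 || sum(!pos) == 0)
    stop("class ", risk_levels()[class_c + 1],
         " lacks positive or negative instances")
  cutoffs <- sort(unique(scores))
  n_pos <- sum(pos)
  pts <- vapply(cutoffs, function(ct) {
    sel <- scores >= ct
    tp <- sum(sel & pos)
    c(recall = tp / n_pos,
      precision = if (sum(sel) == 0) 1 else tp / sum(sel))
  }, numeric(2))
  data.frame(cutoff = cutoffs, recall = pts["recall", ],
             precision = pts["precision", ])
}
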