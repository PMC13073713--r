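test_that("threshold curve has the grid layout and perfect-probability row", {
  y <- rep(0:2, each = 5)
  P <- matrix(0, 15, 3)
  P[cbind(1:15, y + 1)] <- 1
  curve <- threshold_metric_curve(y, P)
  expect_equal(nrow(curve), 9)
  expect_equal(curve$tau, seq(0.1, 0.9, by = 0.1))
  for (cls in c("low", "medium", "high"))
    expect_equal(curve[[paste0("f1_", cls)]], rep(1, 9))
  expect_error(threshold_metric_curve(y, P, numeric(0)), "non-empty")
})

test_that("threshold curve matches hand-computed confusions", {
  # 6 crafted rows; hand-evaluated at tau = 0.3 and tau = 0.6
  y <- c(2, 2, 0, 1, 0, 1)
  P <- rbind(c(0.10, 0.25, 0.65),
             c(0.30, 0.30, 0.40),
             c(0.55, 0.25, 0.20),
             c(0.25, 0.55, 0.20),
             c(0.40, 0.25, 0.35),
             c(0.15, 0.50, 0.35))
  curve <- threshold_metric_curve(y, P, grid = c(0.3, 0.6))
  # tau = 0.3: rows 1,2,5,6 exceed 0.3 on high -> predicted high
  # preds: (2,2,0,1,2,2); high TP=2 FP=2 FN=0 -> P=0.5 R=1 F1=2/3
  r1 <- curve[1, ]
  expect_equal(r1$precision_high, 0.5)
  expect_equal(r1$recall_high, 1)
  expect_equal(r1$f1_high, 2 / 3)
  expect_equal(r1$n_pred_high, 4)
  # tau = 0.6: only row 1 -> preds (2,1,0,1,0,1): tie row 2 -> medium
  r2 <- curve[2, ]
  expect_equal(r2$precision_high, 1)
  expect_equal(r2$recall_high, 0.5)
  expect_equal(r2$f1_high, 2 / 3)
  expect_equal(r2$recall_low, 1)
  expect_equal(r2$precision_medium, 2 / 3)
})

test_that("high-risk recall and prediction count fall as tau rises", {
  set.seed(6)
  y <- sample(0:2, 80, replace = TRUE, prob = c(.4, .5, .1))
  P <- matrix(runif(240), 80, 3)
  P <- P / rowSums(P)
  curve <- threshold_metric_curve(y, P)
  expect_true(all(diff(curve$recall_high) <= 0))
  expect_true(all(diff(curve$n_pred_high) <= 0))
})

test_that("optimal threshold is the first attainment of the max high F1", {
  base <- data.frame(tau = seq(0.1, 0.9, by = 0.1))
  base$f1_high <- c(0.2, 0.4, 0.5, 0.5, 0.7, 0.7, 0.7, 0.6, 0.5)
  expect_equal(select_optimal_threshold(base), 0.5)
  base$f1_high <- rep(0.6, 9)   # constant -> first grid point
  expect_equal(select_optimal_threshold(base), 0.1)
  base$f1_high <- c(0.2, 0.3, 0.4, 0.5, rep(0.8, 5))  # plateau from 0.5
  expect_equal(select_optimal_threshold(base), 0.5)
  # idempotent and order-independent
  shuffled <- base[sample(9), ]
  expect_equal(select_optimal_threshold(shuffled),
               select_optimal_threshold(base))
})

test_that("threshold selection lands at 0.5 on a reference-shaped curve", {
  # emulate the published sweep shape: recall_high flat, precision_high
  # rising to a plateau at tau >= 0.5 -> F1 maximal first at 0.5
  curve <- data.frame(tau = seq(0.1, 0.9, by = 0.1))
  prec <- c(0.55, 0.62, 0.70, 0.76, 0.80, 0.80, 0.80, 0.80, 0.80)
  rec <- rep(0.73, 9)
  curve$f1_high <- 2 * prec * rec / (prec + rec)
  expect_equal(select_optimal_threshold(curve), 0.5)
})

test_that("PR curve equals the exhaustive cutoff enumeration", {
  y <- c(2, 0, 2, 1, 2, 0, 1, 2)
  s <- c(0.9, 0.2, 0.8, 0.4, 0.4, 0.1, 0.6, 0.7)
  got <- precision_recall_curve_ovr(y, s, 2)
  pos <- y == 2
  for (r in seq_len(nrow(got))) {
    sel <- s >= got$cutoff[r]
    expect_equal(got$recall[r], sum(sel & pos) / sum(pos))
    expect_equal(got$precision[r], sum(sel & pos) / sum(sel))
  }
  expect_true(all(diff(got$recall) <= 0))
  # perfectly separating scores -> precision 1 at every attained recall
  sep <- precision_recall_curve_ovr(y, as.numeric(pos), 2)
  expect_true(all(sep$precision[sep$recall > 0] >= 0.5))
  expect_equal(sep$precision[sep$cutoff == 1], 1)
  # constant scores -> single point at (recall 1, precision = prevalence)
  cst <- precision_recall_curve_ovr(y, rep(0.5, 8), 2)
  expect_equal(nrow(cst), 1)
  expect_equal(cst$recall, 1)
  expect_equal(cst$precision, mean(pos))
  expect_error(precision_recall_curve_ovr(c(0, 0), c(.1, .2), 2), "high")
})
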