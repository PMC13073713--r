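test_that("stratified folds are disjoint, exhaustive and class-balanced", {
  y <- rep(0:2, each = 3)
  f <- assign_stratified_folds(y, k = 3, seed = 1)
  expect_setequal(f, 1:3)
  # 3 rows per class, k = 3 -> each fold holds exactly one row of each class
  for (j in 1:3)
    expect_equal(as.integer(table(factor(y[f == j], 0:2))), c(1, 1, 1))
  # 30-row fixture, two seeds: different assignments, both balanced within 1
  y30 <- rep(0:2, times = c(12, 10, 8))
  f1 <- assign_stratified_folds(y30, 3, seed = 1)
  f2 <- assign_stratified_folds(y30, 3, seed = 2)
  expect_false(identical(f1, f2))
  for (f_i in list(f1, f2)) {
    expect_equal(sort(unique(f_i)), 1:3)
    for (cls in 0:2) {
      per <- table(factor(f_i[y30 == cls], 1:3))
      expect_lte(max(per) - min(per), 1)
    }
  }
  expect_error(assign_stratified_folds(c(0, 0, 0, 1, 1, 1, 2, 2), 3),
               "class 2")
})

test_that("prior learner's balanced OOF rows are uniform", {
  # 9 rows, 3 per class: every training complement is exactly balanced
  ft <- make_separated_ft(3)
  folds <- assign_stratified_folds(ft$y, 3, seed = 2)
  blk <- oof_probabilities(learner_spec("prior"), ft, folds)
  expect_equal(unname(blk), matrix(1 / 3, 9, 3))
  expect_equal(colnames(blk), paste0("prior=", c("low", "medium", "high")))
})

test_that("1-NN OOF probabilities recover the true classes on separated data", {
  ft <- make_separated_ft(6)
  folds <- assign_stratified_folds(ft$y, 3, seed = 3)
  blk <- oof_probabilities(learner_spec("1nn"), ft, folds)
  expect_false(anyNA(blk))
  expect_equal(ncol(blk), 3)
  expect_equal(unname(rowSums(blk)), rep(1, 18))
  expect_equal(max.col(blk) - 1L, ft$y)
})

test_that("OOF generation does not leak a row's own label", {
  ft <- make_random_ft(n = 30, d = 4, seed = 6, counts = c(12, 10, 8))
  folds <- assign_stratified_folds(ft$y, 3, seed = 4)
  spec <- learner_spec("LR", seed = 5)
  base <- suppressWarnings(oof_probabilities(spec, ft, folds))
  # corrupt the labels of fold-2 rows: fold 2's model never sees them, so
  # fold-2 OOF rows must be unchanged (other folds' rows may move)
  ft_bad <- ft
  ft_bad$y[folds == 2] <- (ft_bad$y[folds == 2] + 1L) %% 3L
  corrupted <- suppressWarnings(oof_probabilities(spec, ft_bad, folds))
  expect_equal(corrupted[folds == 2, ], base[folds == 2, ])
  expect_false(isTRUE(all.equal(corrupted[folds != 2, ],
                                base[folds != 2, ])))
})

test_that("meta-feature assembly respects width and order contracts", {
  b <- lapply(1:5, function(i) {
    m <- matrix(i, 4, 3)
    colnames(m) <- paste0("L", i, "=", c("low", "medium", "high"))
    m
  })
  Z <- assemble_meta_features(b)
  expect_equal(dim(Z), c(4, 15))
  expect_identical(assemble_meta_features(b[1]), b[[1]])
  Zp <- assemble_meta_features(b[c(2, 1, 3, 4, 5)])
  expect_equal(colnames(Zp)[1:3], colnames(b[[2]]))
  expect_error(assemble_meta_features(list(b[[1]], matrix(0, 3, 3))),
               "row count")
})

test_that("stacked model achieves perfect accuracy on separable data", {
  ft <- make_separated_ft(20)
  model <- fit_stacking_model(ft, list(learner_spec("1nn")),
                              k = 3, seed = 7)
  P <- stacking_predict_proba(model, ft$X)
  expect_equal(max.col(P) - 1L, ft$y)
  expect_equal(unname(rowSums(P)), rep(1, 60), tolerance = 1e-6)
  # duplicate inputs give identical outputs
  X2 <- ft$X[c(1, 1, 31, 31), ]
  P2 <- stacking_predict_proba(model, X2)
  expect_identical(P2[1, ], P2[2, ])
  expect_identical(P2[3, ], P2[4, ])
  expect_error(stacking_predict_proba(model, ft$X[, 1:2]), "columns")
})

test_that("stacking integrates the tree learners end to end", {
  tab <- generate_inspection_records(generator_config(240, seed = 9))
  ff <- build_feature_matrix(tab, feature_schema(), fit = TRUE)
  bal <- smote_tomek_balance(ff$features, smote_config(seed = 1))
  model <- fit_stacking_model(bal, cheap_specs(seed = 2), k = 3, seed = 2)
  expect_equal(model$learner_order,
               c(RF = "RF", GB = "GB", XGBoost = "XGBoost",
                 CatBoost = "CatBoost", LightGBM = "LightGBM"))
  P <- stacking_predict_proba(model, ff$features$X)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-6)
  expect_gt(mean((max.col(P) - 1L) == ff$features$y), 0.5)
})
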