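# R wrappers around the Rcpp tree growers: a Newton-step gradient-boosted
# tree classifier (multinomial deviance, exact greedy splits) and a Gini
# random forest. These back the heterogeneous tree base learners of the
# stacking layer; per-learner hyperparameters (depth, learning rate, row and
# column subsampling, L2 leaf regularization) keep the ensemble diverse.

n_classes <- function() 3L

#' Fit a multinomial gradient-boosted tree model
#'
#' Softmax boosting with one regression tree per class per iteration. Leaf
#' values are Newton steps `-G / (H + lambda)`; split gain is the standard
#' second-order gain. Scores are initialized at smoothed log class priors.
#'
#' @param X Numeric matrix.
#' @param y Integer labels in {0,1,2}.
#' @param n_estimators Number of boosting iterations.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage applied to each tree's leaf values.
#' @param subsample Row fraction sampled (without replacement) per iteration.
#' @param colsample Column fraction sampled per tree.
#' @param lambda L2 regularization added to leaf hessians.
#' @param min_child_weight Minimum hessian sum per child.
#' @param min_leaf Minimum row count per leaf.
#' @param seed Integer seed for the row/column subsampling stream.
#' @return An object of class `gbtree_model`.
#' @export
fit_gbtree <- function(X, y, n_estimators = 150, max_depth = 6,
                       learning_rate = 0.1, subsample = 1, colsample = 1,
                       lambda = 0, min_child_weight = 0, min_leaf = 1,
                       seed = 42) {
  X <- as.matrix(X)
  y <- check_labels(y)
  n <- nrow(X); d <- ncol(X); K <- n_classes()
  counts <- tabulate(y + 1L, nbins = K)
  prior <- log((counts + 1) / (n + K))
  Fmat <- matrix(prior, nrow = n, ncol = K, byrow = TRUE)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y + 1L)] <- 1
  n_sub <- max(2L, as.integer(round(subsample * n)))
  d_sub <- max(1L, as.integer(round(colsample * d)))
  trees <- vector("list", n_estimators)
  with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      P <- softmax_rows(Fmat)
      rows <- if (n_sub < n) sort(sample.int(n, n_sub)) else seq_len(n)
      iter_trees <- vector("list", K)
      for (c in seq_len(K)) {
        cols <- if (d_sub < d) sort(sample.int(d, d_sub)) else seq_len(d)
        g <- P[, c] - Y[, c]
        h <- pmax(P[, c] * (1 - P[, c]), 1e-6)
        tr <- cpp_grow_reg_tree(X, g, h, rows - 1L, cols - 1L,
                                as.integer(max_depth), as.integer(min_leaf),
                                min_child_weight, lambda)
        Fmat[, c] <- Fmat[, c] + learning_rate * cpp_predict_reg_tree(tr, X)
        iter_trees[[c]] <- tr
      }
      trees[[m]] <- iter_trees
    }
  })
  structure(list(trees = trees, prior = prior,
                 learning_rate = learning_rate, n_features = d),
            class = "gbtree_model")
}

#' Predict class probabilities from a gradient-boosted tree model
#'
#' @param model A `gbtree_model`.
#' @param X Numeric matrix with the training column count.
#' @return N x 3 probability matrix (rows sum to 1).
#' @export
predict_gbtree <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("X has ", ncol(X), " columns; model expects ", model$n_features)
  n <- nrow(X); K <- n_classes()
  Fmat <- matrix(model$prior, nrow = n, ncol = K, byrow = TRUE)
  for (iter in model$trees)
    for (c in seq_len(K))
      Fmat[, c] <- Fmat[, c] +
        model$learning_rate * cpp_predict_reg_tree(iter[[c]], X)
  softmax_rows(Fmat)
}

#' Fit a random forest of Gini classification trees
#'
#' Bootstrap rows per tree, `mtry` candidate features per node; prediction
#' averages leaf class distributions across trees. `class_weight =
#' "balanced"` weights each row by `N / (K * n_class)`.
#'
#' @param X Numeric matrix.
#' @param y Integer labels in {0,1,2}.
#' @param n_estimators Number of trees.
#' @param max_depth Maximum depth.
#' @param min_samples_split Minimum rows to attempt a split.
#' @param min_samples_leaf Minimum rows per leaf.
#' @param mtry Features tried per node (default `floor(sqrt(d))`).
#' @param class_weight `"balanced"` or `NULL` for unit weights.
#' @param seed Integer seed.
#' @return An object of class `rf_model`.
#' @export
fit_random_forest <- function(X, y, n_estimators = 150, max_depth = 6,
                              min_samples_split = 2, min_samples_leaf = 1,
                              mtry = NULL, class_weight = "balanced",
                              seed = 42) {
  X <- as.matrix(X)
  y <- check_labels(y)
  n <- nrow(X); d <- ncol(X); K <- n_classes()
  mtry <- as.integer(mtry %||% max(1, floor(sqrt(d))))
  counts <- tabulate(y + 1L, nbins = K)
  w <- if (identical(class_weight, "balanced")) {
    cw <- n / (K * pmax(counts, 1))
    cw[y + 1L]
  } else rep(1, n)
  trees <- vector("list", n_estimators)
  with_seed(seed, {
    for (t in seq_len(n_estimators)) {
      rows <- sample.int(n, n, replace = TRUE)
      node_seed <- sample.int(.Machine$integer.max, 1)
      trees[[t]] <- cpp_grow_class_tree(X, y, w, rows - 1L, K,
                                        as.integer(max_depth),
                                        as.integer(min_samples_leaf),
                                        as.integer(min_samples_split),
                                        mtry, node_seed)
    }
  })
  structure(list(trees = trees, n_features = d), class = "rf_model")
}

#' Predict class probabilities from a random forest
#'
#' @param model An `rf_model`.
#' @param X Numeric matrix with the training column count.
#' @return N x 3 probability matrix (rows sum to 1).
#' @export
predict_random_forest <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("X has ", ncol(X), " columns; model expects ", model$n_features)
  acc <- matrix(0, nrow(X), n_classes())
  for (tr in model$trees) acc <- acc + cpp_predict_class_tree(tr, X)
  acc / length(model$trees)
}
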