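# Pluggable base-learner registry. Each entry provides fit(X, y, params,
# seed) -> model and predict(model, X) -> N x 3 probability matrix. The five
# default tree learners carry the reference hyperparameter settings; extra
# entries (LR, KNN, prior) support the meta-learner, diagnostics and tests.

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner in the registry
#'
#' Lets tests and extensions inject dummy or oracle learners behind the same
#' interface the stacking layer uses.
#'
#' @param name Registry key (matched case-insensitively).
#' @param fit `function(X, y, params, seed)` returning a model object.
#' @param predict_proba `function(model, X)` returning an N x 3 probability
#'   matrix.
#' @param defaults Named list of default hyperparameters.
#' @return `name`, invisibly.
#' @export
register_learner <- function(name, fit, predict_proba, defaults = list()) {
  assign(tolower(name),
         list(fit = fit, predict_proba = predict_proba, defaults = defaults),
         envir = .learner_registry)
  invisible(name)
}

get_learner <- function(name) {
  key <- tolower(name)
  if (key %in% c("svm", "mlp"))
    stop("learner '", name, "' requires libraries not available in this ",
         "build; supported learners: ", paste(list_learners(), collapse = ", "))
  if (!exists(key, envir = .learner_registry))
    stop("unknown learner '", name, "'; registered: ",
         paste(list_learners(), collapse = ", "))
  get(key, envir = .learner_registry)
}

#' List registered learner names
#' @return Character vector of registry keys.
#' @export
list_learners <- function() sort(ls(.learner_registry))

#' Learner specification
#'
#' @param name Learner name resolved in the registry (e.g. `"RF"`,
#'   `"XGBoost"`, `"LR"`).
#' @param params Named list of hyperparameter overrides (defaults are the
#'   registry's reference settings).
#' @param seed Integer seed for this learner's fits.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(name, params = list(), seed = 42) {
  entry <- get_learner(name)  # validates resolvability now
  merged <- utils::modifyList(entry$defaults, params)
  structure(list(name = name, params = merged, seed = as.integer(seed)),
            class = "learner_spec")
}

#' Fit a learner spec on a feature matrix
#'
#' @param spec A [learner_spec()].
#' @param X Numeric matrix.
#' @param y Integer labels in {0,1,2}.
#' @param seed Optional seed override (defaults to `spec$seed`).
#' @return A `fitted_learner` object.
#' @export
fit_learner <- function(spec, X, y, seed = NULL) {
  entry <- get_learner(spec$name)
  model <- entry$fit(as.matrix(X), check_labels(y), spec$params,
                     seed %||% spec$seed)
  structure(list(name = spec$name, model = model, n_features = ncol(X)),
            class = "fitted_learner")
}

#' Predict class probabilities from a fitted learner
#'
#' @param fit A `fitted_learner`.
#' @param X Numeric matrix with the training column count.
#' @return N x 3 probability matrix; rows sum to 1.
#' @export
predict_learner <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != fit$n_features)
    stop("X has ", ncol(X), " columns; learner '", fit$name,
         "' was fitted on ", fit$n_features)
  entry <- get_learner(fit$name)
  P <- entry$predict_proba(fit$model, X)
  colnames(P) <- risk_levels()
  normalize_prob_rows(P)
}

#' Default base-learner specifications
#'
#' The five heterogeneous tree learners of the stacking first layer, each
#' with its reference hyperparameters (150 estimators; RF depth 6 balanced
#' class weights; GB depth 5 lr 0.1; XGBoost depth 6 lr 0.05 subsample 0.8
#' colsample 0.8 lambda 1; CatBoost depth 6 lr 0.1 L2 3; LightGBM depth 6
#' lr 0.1 subsample 0.8 colsample 0.8 min-child 20).
#'
#' @param seed Base seed; learner m gets `seed + m`.
#' @param n_estimators Optional override of the tree count for every
#'   learner, used to scale compute down in constrained runs.
#' @return List of [learner_spec()] objects in fixed order.
#' @export
default_base_specs <- function(seed = 42, n_estimators = NULL) {
  nms <- c("RF", "GB", "XGBoost", "CatBoost", "LightGBM")
  specs <- lapply(seq_along(nms), function(m) {
    params <- if (is.null(n_estimators)) list()
              else list(n_estimators = as.integer(n_estimators))
    learner_spec(nms[m], params = params, seed = seed + m)
  })
  names(specs) <- nms
  specs
}

# --- registry population (runs at load time) -------------------------------

register_default_learners <- function() {
  register_learner(
    "RF",
    fit = function(X, y, p, seed)
      fit_random_forest(X, y, n_estimators = p$n_estimators,
                        max_depth = p$max_depth,
                        min_samples_split = p$min_samples_split,
                        min_samples_leaf = p$min_samples_leaf,
                        mtry = p$mtry, class_weight = p$class_weight,
                        seed = seed),
    predict_proba = predict_random_forest,
    defaults = list(n_estimators = 150L, max_depth = 6L,
                    min_samples_split = 2L, min_samples_leaf = 1L,
                    mtry = NULL, class_weight = "balanced"))

  gb_fit <- function(X, y, p, seed)
    fit_gbtree(X, y, n_estimators = p$n_estimators, max_depth = p$max_depth,
               learning_rate = p$learning_rate, subsample = p$subsample,
               colsample = p$colsample, lambda = p$lambda,
               min_child_weight = p$min_child_weight,
               min_leaf = p$min_leaf, seed = seed)

  register_learner(
    "GB", fit = gb_fit, predict_proba = predict_gbtree,
    defaults = list(n_estimators = 150L, max_depth = 5L, learning_rate = 0.1,
                    subsample = 1, colsample = 1, lambda = 0,
                    min_child_weight = 0, min_leaf = 1L))
  register_learner(
    "XGBoost", fit = gb_fit, predict_proba = predict_gbtree,
    defaults = list(n_estimators = 150L, max_depth = 6L, learning_rate = 0.05,
                    subsample = 0.8, colsample = 0.8, lambda = 1,
                    min_child_weight = 1, min_leaf = 1L))
  register_learner(
    "CatBoost", fit = gb_fit, predict_proba = predict_gbtree,
    defaults = list(n_estimators = 150L, max_depth = 6L, learning_rate = 0.1,
                    subsample = 1, colsample = 1, lambda = 3,
                    min_child_weight = 0, min_leaf = 1L))
  register_learner(
    "LightGBM", fit = gb_fit, predict_proba = predict_gbtree,
    defaults = list(n_estimators = 150L, max_depth = 6L, learning_rate = 0.1,
                    subsample = 0.8, colsample = 0.8, lambda = 0,
                    min_child_weight = 0, min_leaf = 20L))

  # Multinomial logistic regression (ridge penalty). The meta-learner of the
  # stacking layer; glmnet lambda = 1/N matches unit inverse regularization
  # strength under glmnet's 1/N loss scaling.
  register_learner(
    "LR",
    fit = function(X, y, p, seed) {
      classes <- sort(unique(y))
      if (length(classes) < 2)
        return(list(degenerate = classes[1]))
      lam <- p$lambda %||% (1 / nrow(X))
      fit <- with_seed(seed,
        glmnet::glmnet(X, factor(y, levels = classes),
                       family = "multinomial", alpha = p$alpha %||% 0,
                       lambda = c(lam * 10, lam), standardize = FALSE))
      list(fit = fit, classes = classes, lambda = lam)
    },
    predict_proba = function(model, X) {
      P <- matrix(0, nrow(X), 3)
      if (!is.null(model$degenerate)) {
        P[, model$degenerate + 1L] <- 1
        return(P)
      }
      pr <- stats::predict(model$fit, X, s = model$lambda, type = "response")
      P[, model$classes + 1L] <- pr[, , 1]
      P
    },
    defaults = list(alpha = 0, lambda = NULL))

  # Exact k-nearest-neighbor probabilities (uniform weights, ties broken by
  # training row index).
  register_learner(
    "KNN",
    fit = function(X, y, p, seed)
      list(X = X, y = y, k = p$n_neighbors %||% 5L),
    predict_proba = function(model, X) {
      k <- min(model$k, nrow(model$X))
      D <- dist_matrix(X, model$X)
      P <- matrix(0, nrow(X), 3)
      for (i in seq_len(nrow(X))) {
        nb <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
        P[i, ] <- tabulate(model$y[nb] + 1L, nbins = 3) / k
      }
      P
    },
    defaults = list(n_neighbors = 5L))

  # Dummy prior learner: predicts training class frequencies everywhere.
  # Useful as a no-information diagnostic and in tests.
  register_learner(
    "prior",
    fit = function(X, y, p, seed)
      list(freq = tabulate(y + 1L, nbins = 3) / length(y)),
    predict_proba = function(model, X)
      matrix(model$freq, nrow(X), 3, byrow = TRUE),
    defaults = list())
}
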