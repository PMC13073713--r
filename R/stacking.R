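# Stacked generalization: stratified k-fold out-of-fold probability
# meta-features from M heterogeneous base learners, fused by a multinomial
# logistic meta-learner; base learners are refit on the full table for
# inference.

#' Stratified fold assignment
#'
#' Assigns each row to one of `k` folds so folds are disjoint, exhaustive
#' and per-class balanced within one row.
#'
#' @param y Integer labels in {0,1,2}.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per row.
#' @export
assign_stratified_folds <- function(y, k = 3, seed = 42) {
  y <- check_labels(y)
  k <- as.integer(k)
  if (k < 2) stop("k must be >= 2")
  counts <- table(factor(y, levels = 0:2))
  short <- which(counts < k) - 1L
  if (length(short) > 0)
    stop("class ", paste(short, collapse = ", "),
         " has fewer rows than k = ", k)
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in 0:2) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Out-of-fold probability block for one base learner
#'
#' For each fold, the learner is trained with that fold excluded and
#' predicts the held-out rows, so every row's probabilities come from a
#' model that never saw it.
#'
#' @param spec A [learner_spec()].
#' @param ft A [feature_table()] with labels.
#' @param folds Fold assignment from [assign_stratified_folds()].
#' @return N x 3 probability matrix (columns `<name>=low/medium/high`).
#' @export
oof_probabilities <- function(spec, ft, folds) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$y))
  if (length(folds) != nrow(ft$X)) stop("folds length must match rows")
  out <- matrix(NA_real_, nrow(ft$X), 3)
  for (j in sort(unique(folds))) {
    hold <- folds == j
    fit <- tryCatch(
      fit_learner(spec, ft$X[!hold, , drop = FALSE], ft$y[!hold],
                  seed = spec$seed + j),
      error = function(e)
        stop("base learner '", spec$name, "' failed on fold ", j, ": ",
             conditionMessage(e)))
    out[hold, ] <- predict_learner(fit, ft$X[hold, , drop = FALSE])
  }
  if (anyNA(out)) stop("out-of-fold matrix has unfilled rows")
  colnames(out) <- paste(spec$name, risk_levels(), sep = "=")
  out
}

#' Assemble per-learner probability blocks into the meta-feature matrix
#'
#' @param blocks List of N x 3 blocks in learner order.
#' @return N x 3M matrix (horizontal concatenation).
#' @export
assemble_meta_features <- function(blocks) {
  if (length(blocks) == 0) stop("no blocks supplied")
  n <- unique(vapply(blocks, nrow, integer(1)))
  if (length(n) != 1) stop("blocks differ in row count")
  do.call(cbind, blocks)
}

#' Fit a stacking model
#'
#' Generates stratified out-of-fold meta-features from every base learner,
#' trains the meta-learner on them, then refits each base learner on the
#' full table for inference (fold models are not retained).
#'
#' @param ft A [feature_table()] with labels (balanced or not).
#' @param base_specs List of [learner_spec()] objects (order is recorded).
#' @param meta_spec Meta-learner spec (default multinomial logistic
#'   regression).
#' @param k Number of folds (default 3).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `stacking_model`.
#' @export
fit_stacking_model <- function(ft, base_specs,
                               meta_spec = learner_spec("LR"),
                               k = 3, seed = 42) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$y))
  folds <- assign_stratified_folds(ft$y, k = k, seed = seed)
  blocks <- lapply(base_specs, oof_probabilities, ft = ft, folds = folds)
  Z <- assemble_meta_features(blocks)
  meta_fit <- fit_learner(meta_spec, Z, ft$y, seed = meta_spec$seed)
  refits <- lapply(base_specs, function(sp) fit_learner(sp, ft$X, ft$y))
  structure(list(base_specs = base_specs,
                 learner_order = vapply(base_specs, `[[`, "", "name"),
                 refit_models = refits,
                 meta_fit = meta_fit,
                 meta_spec = meta_spec,
                 folds = folds,
                 n_features = ncol(ft$X)),
            class = "stacking_model")
}

#' Fused class probabilities from a stacking model
#'
#' Base probabilities come from the full-data refit models, concatenated in
#' the recorded learner order and passed through the meta-learner.
#'
#' @param model A `stacking_model`.
#' @param X Numeric matrix with the training column count.
#' @return N x 3 probability matrix; rows sum to 1.
#' @export
stacking_predict_proba <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("X has ", ncol(X), " columns; model expects ", model$n_features)
  blocks <- lapply(seq_along(model$refit_models), function(m) {
    B <- predict_learner(model$refit_models[[m]], X)
    colnames(B) <- paste(model$learner_order[m], risk_levels(), sep = "=")
    B
  })
  Z <- assemble_meta_features(blocks)
  P <- predict_learner(model$meta_fit, Z)
  colnames(P) <- risk_levels()
  P
}
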