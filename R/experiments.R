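# Experiment harnesses: benchmark of the framework against unresampled
# single-tree baselines on a shared split, and robustness across test-set
# fractions. All runs are reproducible from the config seeds.

#' Experiment configuration
#'
#' @param generator A [generator_config()] describing the synthetic table.
#' @param schema A [feature_schema()] (fitted on the training partition).
#' @param ensemble An [ensemble_config()] for the full framework.
#' @param baselines List of [learner_spec()]s trained without any resampling
#'   (default: the five tree learners).
#' @param test_fraction Split fraction for the benchmark (default 0.2).
#' @param fractions Test fractions for the robustness study.
#' @param seed Seed for the splits.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(),
                              schema = feature_schema(),
                              ensemble = ensemble_config(),
                              baselines = default_base_specs(),
                              test_fraction = 0.2,
                              fractions = c(0.1, 0.2, 0.4),
                              seed = 42) {
  if (any(fractions <= 0 | fractions >= 1))
    stop("fractions must lie strictly between 0 and 1")
  structure(list(generator = generator, schema = schema, ensemble = ensemble,
                 baselines = baselines, test_fraction = test_fraction,
                 fractions = fractions, seed = as.integer(seed)),
            class = "experiment_config")
}

argmax_labels <- function(P) as.integer(max.col(P, ties.method = "last") - 1L)

metric_row <- function(model_name, y_true, y_pred, P) {
  rep_ <- suppressWarnings(classification_report(y_true, y_pred))
  auc <- roc_auc_ovr(y_true, P)
  data.frame(model = model_name,
             precision_high = rep_$precision[["high"]],
             recall_high = rep_$recall[["high"]],
             f1_high = rep_$f1[["high"]],
             auc_high = auc$auc[["high"]],
             precision_medium = rep_$precision[["medium"]],
             recall_medium = rep_$recall[["medium"]],
             f1_medium = rep_$f1[["medium"]],
             auc_medium = auc$auc[["medium"]],
             precision_low = rep_$precision[["low"]],
             recall_low = rep_$recall[["low"]],
             f1_low = rep_$f1[["low"]],
             auc_low = auc$auc[["low"]],
             accuracy = rep_$accuracy,
             weighted_f1 = rep_$weighted_f1,
             macro_f1 = rep_$macro_f1,
             macro_auc = auc$macro_auc,
             stringsAsFactors = FALSE)
}

# shared pipeline front end: generate, split, featurize
prepare_split <- function(cfg, test_fraction) {
  records <- generate_inspection_records(cfg$generator)
  split <- stratified_split(records, test_fraction, seed = cfg$seed)
  fit <- build_feature_matrix(split$train, cfg$schema, fit = TRUE)
  test_ft <- build_feature_matrix(split$test, fit$schema, fit = FALSE)
  list(train = fit$features, test = test_ft, schema = fit$schema)
}

#' Benchmark the framework against unresampled single-learner baselines
#'
#' Trains every baseline (no resampling, plain argmax decisions) and the
#' full bagging-stacking framework on the same stratified split, and
#' reports one row of test-set metrics per model. A failing model is
#' recorded with an `error` note and the run continues.
#'
#' @param cfg An [experiment_config()].
#' @return data.frame with one row per model (baselines + `Bagging-Stacking`)
#'   and the full metric layout; failed models carry `NA` metrics and a
#'   non-`NA` `error` column.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  parts <- prepare_split(cfg, cfg$test_fraction)
  y_test <- parts$test$y
  rows <- list()
  for (sp in cfg$baselines) {
    rows[[sp$name]] <- tryCatch({
      fit <- fit_learner(sp, parts$train$X, parts$train$y)
      P <- predict_learner(fit, parts$test$X)
      r <- metric_row(sp$name, y_test, argmax_labels(P), P)
      r$error <- NA_character_
      r
    }, error = function(e) {
      r <- metric_row(sp$name, y_test, y_test, diag(3)[y_test + 1L, ])
      r[, -1] <- NA_real_
      r$error <- conditionMessage(e)
      r
    })
  }
  framework <- tryCatch({
    model <- fit_bagging_stacking(parts$train, cfg$ensemble)
    pred <- predict(model, parts$test$X)
    r <- metric_row("Bagging-Stacking", y_test, pred$labels, pred$proba)
    r$error <- NA_character_
    r
  }, error = function(e) {
    r <- metric_row("Bagging-Stacking", y_test, y_test,
                    diag(3)[y_test + 1L, ])
    r[, -1] <- NA_real_
    r$error <- conditionMessage(e)
    r
  })
  out <- do.call(rbind, c(rows, list(framework)))
  rownames(out) <- NULL
  out
}

#' Robustness of the framework across test-set fractions
#'
#' For each test fraction, draws a fresh stratified split, runs the full
#' pipeline and collects per-class F1, precision, recall and AUC.
#'
#' @param cfg An [experiment_config()].
#' @return Long data.frame with columns `fraction`, `class`, `metric`,
#'   `value` (|fractions| x 3 classes x 4 metrics rows).
#' @export
run_robustness <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  out <- list()
  for (frac in cfg$fractions) {
    parts <- prepare_split(cfg, frac)
    model <- fit_bagging_stacking(parts$train, cfg$ensemble)
    pred <- predict(model, parts$test$X)
    rep_ <- suppressWarnings(classification_report(parts$test$y, pred$labels))
    auc <- roc_auc_ovr(parts$test$y, pred$proba)
    for (cls in risk_levels()) {
      out[[length(out) + 1]] <- data.frame(
        fraction = frac,
        class = cls,
        metric = c("f1", "precision", "recall", "auc"),
        value = c(rep_$f1[[cls]], rep_$precision[[cls]],
                  rep_$recall[[cls]], auc$auc[[cls]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
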