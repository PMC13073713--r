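# The full framework: B stacking models fitted on B balanced subsets
# (stratified bootstrap + SMOTE-Tomek), fused by soft voting, with an
# independent probability threshold for the high-risk class.

#' Ensemble configuration
#'
#' All framework constants: bag count `B` (default 5), fold count `k`
#' (default 3), high-risk threshold `tau` (default 0.5), whether each bag
#' draws a stratified bootstrap before balancing (default `TRUE`; turning it
#' off leaves SMOTE randomness as the only source of bag diversity), the
#' SMOTE settings, the base and meta learner specs, the decision rule and
#' the master seed (per-bag seeds are `seed + b`).
#'
#' @param B Number of bags (>= 1).
#' @param k Folds for out-of-fold meta-features.
#' @param tau High-risk probability threshold in [0, 1].
#' @param bootstrap Draw a stratified bootstrap per bag before balancing.
#' @param smote A [smote_config()].
#' @param base_specs List of base [learner_spec()]s (default: the five tree
#'   learners).
#' @param meta_spec Meta-learner spec (default multinomial logistic).
#' @param decision_rule `"threshold"` for the high-risk threshold rule,
#'   `"argmax"` for the plain argmax ablation.
#' @param seed Master seed.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(B = 5, k = 3, tau = 0.5, bootstrap = TRUE,
                            smote = smote_config(),
                            base_specs = default_base_specs(),
                            meta_spec = learner_spec("LR"),
                            decision_rule = c("threshold", "argmax"),
                            seed = 42) {
  decision_rule <- match.arg(decision_rule)
  if (B < 1) stop("B must be >= 1")
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  structure(list(B = as.integer(B), k = as.integer(k), tau = tau,
                 bootstrap = isTRUE(bootstrap), smote = smote,
                 base_specs = base_specs, meta_spec = meta_spec,
                 decision_rule = decision_rule, seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Fit the bagging-stacking framework
#'
#' For each bag b = 1..B: derive seed `seed + b`, optionally draw a
#' stratified bootstrap of the training table, balance it with SMOTE-Tomek,
#' and fit a complete stacking model. All B members are retained.
#'
#' @param ft Training [feature_table()] with labels (all classes present,
#'   each with at least `k` rows).
#' @param cfg An [ensemble_config()].
#' @return An object of class `bagging_stacking_model`.
#' @export
fit_bagging_stacking <- function(ft, cfg = ensemble_config()) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$y),
            inherits(cfg, "ensemble_config"))
  members <- vector("list", cfg$B)
  subset_signatures <- character(cfg$B)
  for (b in seq_len(cfg$B)) {
    seed_b <- cfg$seed + b
    res <- tryCatch({
      ft_b <- if (cfg$bootstrap) stratified_bootstrap(ft, seed = seed_b)
              else ft
      balanced <- smote_tomek_balance(
        ft_b, smote_config(cfg$smote$k_neighbors, seed = seed_b))
      # shift learner seeds per bag so members are independently reproducible
      specs_b <- lapply(cfg$base_specs, function(sp) {
        sp$seed <- sp$seed + 1000L * b
        sp
      })
      meta_b <- cfg$meta_spec
      meta_b$seed <- meta_b$seed + 1000L * b
      list(model = fit_stacking_model(balanced, specs_b, meta_b,
                                      k = cfg$k, seed = seed_b),
           sig = paste(digest_rows(balanced), collapse = ""))
    }, error = function(e)
      stop("bag ", b, " failed: ", conditionMessage(e)))
    members[[b]] <- res$model
    subset_signatures[b] <- res$sig
  }
  structure(list(members = members, config = cfg,
                 subset_signatures = subset_signatures),
            class = "bagging_stacking_model")
}

# cheap deterministic signature of a balanced subset (for diversity checks)
digest_rows <- function(ft) {
  format(sum(ft$X * seq_len(length(ft$X))) + sum(ft$y) + nrow(ft$X),
         digits = 15)
}

#' Soft-voting aggregation of member probability matrices
#'
#' Element-wise arithmetic mean of B equally shaped probability matrices.
#'
#' @param member_probs List of N x 3 probability matrices.
#' @return N x 3 probability matrix (rows still sum to 1).
#' @export
soft_vote <- function(member_probs) {
  if (length(member_probs) == 0) stop("no member probabilities supplied")
  dims <- unique(lapply(member_probs, dim))
  if (length(dims) != 1) stop("member probability matrices differ in shape")
  Reduce(`+`, member_probs) / length(member_probs)
}

#' High-risk threshold decision rule
#'
#' A row is labelled high (2) iff its high-risk probability strictly exceeds
#' `tau`; otherwise the label is the argmax over low and medium only (exact
#' tie goes to medium, the risk-conservative side). High can therefore be
#' predicted only through the threshold.
#'
#' @param P_final N x 3 probability matrix (low, medium, high).
#' @param tau Threshold in [0, 1].
#' @return Integer label vector in {0,1,2}.
#' @export
decide_labels <- function(P_final, tau = 0.5) {
  P_final <- as.matrix(P_final)
  if (ncol(P_final) != 3) stop("P_final must have 3 columns")
  high <- P_final[, 3] > tau
  lab <- ifelse(P_final[, 1] > P_final[, 2], 0L, 1L)  # tie -> medium
  lab[high] <- 2L
  as.integer(lab)
}

#' Predict with the bagging-stacking framework
#'
#' Member stacking probabilities are soft-voted and the configured decision
#' rule (high-risk threshold, or plain argmax for ablation) is applied.
#'
#' @param object A `bagging_stacking_model`.
#' @param X Numeric matrix with the training column count.
#' @param tau Threshold override (defaults to the fitted config's `tau`).
#' @param ... Unused.
#' @return List of class `risk_prediction` with elements `labels`,
#'   `proba` (the soft-voted matrix), `member_proba` (list of member
#'   matrices) and `tau`.
#' @export
predict.bagging_stacking_model <- function(object, X, tau = NULL, ...) {
  tau <- tau %||% object$config$tau
  member <- lapply(object$members, function(m) stacking_predict_proba(m, X))
  P <- soft_vote(member)
  labels <- if (object$config$decision_rule == "argmax")
    as.integer(max.col(P, ties.method = "last") - 1L)
  else decide_labels(P, tau)
  structure(list(labels = labels, proba = P, member_proba = member,
                 tau = tau),
            class = "risk_prediction")
}

#' Save / load a fitted framework bundle
#'
#' Runtime serialization of a fitted model (RDS container). Provided for the
#' command-line workflow; bundles are artifacts, not package data.
#'
#' @param model A `bagging_stacking_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
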