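# Shared fixtures and injected test learners.

# Exact 1-nearest-neighbor learner: on well-separated fixtures it acts as an
# oracle (training rows match themselves, held-out rows match their cluster).
register_learner(
  "1nn",
  fit = function(X, y, p, seed) list(X = X, y = y),
  predict_proba = function(model, X) {
    P <- matrix(0, nrow(X), 3)
    for (i in seq_len(nrow(X))) {
      d <- colSums((t(model$X) - X[i, ])^2)
      P[i, model$y[which.min(d)] + 1L] <- 1
    }
    P
  })

# Three well-separated Gaussian clusters, one per class.
make_separated_ft <- function(n_per_class = 10, d = 4, seed = 1, sd = 0.05) {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  set.seed(seed)
  X <- do.call(rbind, lapply(1:3, function(k) {
    base <- matrix(rep(centers[k, ], each = n_per_class), n_per_class, 2)
    cbind(base + matrix(rnorm(n_per_class * 2, sd = sd), n_per_class, 2),
          matrix(rnorm(n_per_class * (d - 2)), n_per_class, d - 2))
  }))
  colnames(X) <- paste0("f", seq_len(d))
  feature_table(X, rep(0:2, each = n_per_class))
}

# Random labelled table for property tests.
make_random_ft <- function(n = 30, d = 4, seed = 1,
                           counts = c(12, 10, 8)) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  feature_table(X, sample(rep(0:2, times = counts))[seq_len(n)])
}

# All-pairs brute-force Tomek oracle: mutual single nearest neighbors
# (ties -> lowest index) with different labels.
brute_tomek <- function(X, y) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- integer(n)
  for (i in 1:n) nn[i] <- which.min(D[i, ])
  out <- NULL
  for (i in 1:n) for (j in 1:n)
    if (i < j && nn[i] == j && nn[j] == i && y[i] != y[j])
      out <- rbind(out, c(i, j))
  out
}

# Mann-Whitney pair-counting AUC oracle (concordant + half ties).
brute_auc <- function(score, pos) {
  sp <- score[pos]; sn <- score[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Fast scaled learner profile for pipeline tests.
cheap_specs <- function(seed = 1, n_estimators = 15) {
  default_base_specs(seed = seed, n_estimators = n_estimators)
}
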