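# Hybrid resampling: per-class SMOTE oversampling to the majority count,
# Tomek-link boundary cleaning, and stratified bootstrap for bagging.

#' SMOTE configuration
#'
#' @param k_neighbors Number of same-class nearest neighbors interpolation
#'   partners are drawn from (effective k shrinks to class size - 1 for tiny
#'   classes).
#' @param seed Integer seed.
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5, seed = 42) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "smote_config")
}

# Squared Euclidean distance matrix (small-n exact computation).
dist_matrix <- function(X, Y = X) {
  sq_x <- rowSums(X^2)
  sq_y <- rowSums(Y^2)
  D <- outer(sq_x, sq_y, "+") - 2 * X %*% t(Y)
  D[D < 0] <- 0
  D
}

#' SMOTE oversampling of one minority class
#'
#' Generates `n_new` synthetic rows `x_i + lambda * (x_j - x_i)` where `x_i`
#' is drawn uniformly from the minority rows, `x_j` uniformly from the k
#' nearest minority neighbors of `x_i` (Euclidean distance, ties broken by
#' row index), and `lambda ~ U(0, 1)`.
#'
#' @param X_minority Numeric matrix of minority-class rows.
#' @param n_new Number of synthetic rows to generate (>= 0).
#' @param cfg A [smote_config()].
#' @return Matrix with `n_new` rows (0-row matrix when `n_new = 0`). A single
#'   minority row falls back to exact duplication with a warning.
#' @export
smote_oversample <- function(X_minority, n_new, cfg = smote_config()) {
  X_minority <- as.matrix(X_minority)
  if (nrow(X_minority) == 0) stop("cannot oversample an empty class")
  if (n_new < 0) stop("n_new must be >= 0")
  if (n_new == 0)
    return(X_minority[integer(0), , drop = FALSE])
  if (nrow(X_minority) == 1) {
    warning("single-member class: SMOTE falls back to exact duplication")
    return(X_minority[rep(1, n_new), , drop = FALSE])
  }
  n <- nrow(X_minority)
  k_eff <- min(cfg$k_neighbors, n - 1)
  D <- dist_matrix(X_minority)
  diag(D) <- Inf
  # k nearest same-class neighbors per row, deterministic tie-break by index
  # (explicit rbind keeps the matrix shape when k_eff = 1)
  nn <- do.call(rbind, lapply(seq_len(n), function(i)
    order(D[i, ], seq_len(n))[seq_len(k_eff)]))
  with_seed(cfg$seed, {
    i <- sample.int(n, n_new, replace = TRUE)
    j_pick <- sample.int(k_eff, n_new, replace = TRUE)
    lambda <- stats::runif(n_new)
    j <- nn[cbind(i, j_pick)]
    X_minority[i, , drop = FALSE] +
      lambda * (X_minority[j, , drop = FALSE] - X_minority[i, , drop = FALSE])
  })
}

#' Find Tomek links
#'
#' Returns the unordered pairs (i, j) with different labels in which each row
#' is the other's single nearest neighbor under Euclidean distance over the
#' whole table (nearest-neighbor ties broken by lowest index), ordered by
#' (min index, max index).
#'
#' @param X Numeric matrix (>= 2 rows).
#' @param y Label vector aligned with `X`.
#' @return data.frame with columns `index_a`, `index_b`, `class_a`, `class_b`
#'   (`index_a < index_b`); zero rows when no links exist.
#' @export
find_tomek_links <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to search for Tomek links")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  D <- dist_matrix(X)
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)  # which.min breaks ties by lowest index
  a <- integer(0); b <- integer(0)
  for (i in seq_len(nrow(X))) {
    j <- nn[i]
    if (i < j && nn[j] == i && y[i] != y[j]) {
      a <- c(a, i); b <- c(b, j)
    }
  }
  data.frame(index_a = a, index_b = b,
             class_a = y[a], class_b = y[b])
}

#' SMOTE-Tomek balancing of a feature table
#'
#' First raises every non-majority class to the majority count with SMOTE
#' (neighbors sought within the same class only), then computes Tomek links
#' on the augmented table and removes, from each link, the member whose
#' class currently has the larger row count (ties remove neither member;
#' counts are updated as removals proceed, in link order).
#'
#' @param ft A [feature_table()] with labels; every class present.
#' @param cfg A [smote_config()].
#' @return A balanced `feature_table` with attribute `"n_removed"` (number of
#'   Tomek-link removals).
#' @export
smote_tomek_balance <- function(ft, cfg = smote_config()) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$y))
  counts <- table(factor(ft$y, levels = 0:2))
  if (any(counts == 0)) stop("every class must be present")
  target <- max(counts)
  X_aug <- ft$X
  y_aug <- ft$y
  for (cls in 0:2) {
    need <- target - counts[[as.character(cls)]]
    if (need > 0) {
      Xc <- ft$X[ft$y == cls, , drop = FALSE]
      syn <- smote_oversample(Xc, need,
                              smote_config(cfg$k_neighbors,
                                           seed = cfg$seed + cls))
      X_aug <- rbind(X_aug, syn)
      y_aug <- c(y_aug, rep(cls, need))
    }
  }
  links <- find_tomek_links(X_aug, y_aug)
  drop <- integer(0)
  cur <- table(factor(y_aug, levels = 0:2))
  if (nrow(links) > 0) {
    for (r in seq_len(nrow(links))) {
      ca <- links$class_a[r]; cb <- links$class_b[r]
      na <- cur[[as.character(ca)]]; nb <- cur[[as.character(cb)]]
      if (na == nb) next
      victim <- if (na > nb) links$index_a[r] else links$index_b[r]
      vcls <- if (na > nb) ca else cb
      drop <- c(drop, victim)
      cur[[as.character(vcls)]] <- cur[[as.character(vcls)]] - 1L
    }
  }
  if (length(drop) > 0) {
    X_aug <- X_aug[-drop, , drop = FALSE]
    y_aug <- y_aug[-drop]
  }
  out <- feature_table(X_aug, y_aug)
  attr(out, "n_removed") <- length(drop)
  out
}

#' Stratified bootstrap of a feature table
#'
#' Samples rows with replacement within each class, preserving per-class
#' counts exactly, so the output has the input's size and class composition.
#'
#' @param ft A [feature_table()] with labels.
#' @param seed Integer seed.
#' @return A `feature_table` of the same size and class counts.
#' @export
stratified_bootstrap <- function(ft, seed = 42) {
  stopifnot(inherits(ft, "feature_table"), !is.null(ft$y))
  counts <- table(factor(ft$y, levels = 0:2))
  if (any(counts == 0)) stop("every class must be present")
  with_seed(seed, {
    idx <- integer(0)
    for (cls in 0:2) {
      pool <- which(ft$y == cls)
      # sample.int avoids R's 1:n surprise when pool has a single element
      idx <- c(idx, pool[sample.int(length(pool), length(pool),
                                    replace = TRUE)])
    }
    feature_table(ft$X[idx, , drop = FALSE], ft$y[idx])
  })
}
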