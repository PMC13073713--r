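test_that("SMOTE synthetics are convex combinations of minority rows", {
  X <- rbind(c(0, 0), c(2, 2))
  syn <- smote_oversample(X, 5, smote_config(seed = 1))
  expect_equal(nrow(syn), 5)
  # segment property: every point is (t, t) with t in [0, 2]
  expect_equal(syn[, 1], syn[, 2])
  expect_true(all(syn >= 0 & syn <= 2))
  # identical minority rows -> synthetics equal that point
  Xd <- matrix(1, 4, 3)
  expect_true(all(smote_oversample(Xd, 6, smote_config(seed = 2)) == 1))
  # lambda recoverable on a general 2-point fixture
  Xg <- rbind(c(1, 5), c(3, 1))
  syn2 <- smote_oversample(Xg, 20, smote_config(seed = 3))
  lam <- (syn2[, 1] - 1) / 2
  on_seg1 <- abs(syn2[, 2] - (5 - 4 * lam)) < 1e-12 & lam >= 0 & lam <= 1
  lam_b <- (syn2[, 1] - 3) / (-2)
  on_seg2 <- abs(syn2[, 2] - (1 + 4 * lam_b)) < 1e-12 & lam_b >= 0 & lam_b <= 1
  expect_true(all(on_seg1 | on_seg2))
})

test_that("SMOTE edge cases: empty output, duplication fallback, errors", {
  X <- rbind(c(0, 0), c(1, 1))
  expect_equal(nrow(smote_oversample(X, 0)), 0)
  expect_warning(dup <- smote_oversample(X[1, , drop = FALSE], 3,
                                         smote_config(seed = 1)),
                 "duplication")
  expect_equal(unname(dup), matrix(0, 3, 2))
  expect_error(smote_oversample(X[integer(0), , drop = FALSE], 1), "empty")
  # determinism
  expect_identical(smote_oversample(X, 4, smote_config(seed = 9)),
                   smote_oversample(X, 4, smote_config(seed = 9)))
})

test_that("Tomek links match the all-pairs brute-force oracle", {
  # 1-D fixture: maj at 0.0 and 1.0, min at 1.1 -> single link (2, 3)
  X <- matrix(c(0, 1, 1.1), ncol = 1)
  links <- find_tomek_links(X, c(0, 0, 1))
  expect_equal(links$index_a, 2L)
  expect_equal(links$index_b, 3L)
  # two tight same-class clusters far apart -> no links
  Xc <- rbind(matrix(rnorm(10, sd = .01), 5), matrix(5 + rnorm(10, sd = .01), 5))
  expect_equal(nrow(find_tomek_links(Xc, rep(c(0, 1), each = 5))), 0)
  # one point per class -> that pair
  l2 <- find_tomek_links(rbind(c(0, 0), c(9, 9)), c(0, 2))
  expect_equal(c(l2$index_a, l2$index_b), c(1L, 2L))
  # 100 random tables vs oracle
  set.seed(7)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    d <- sample(1:5, 1)
    Xi <- matrix(rnorm(n * d), n, d)
    yi <- sample(0:2, n, replace = TRUE)
    got <- find_tomek_links(Xi, yi)
    want <- brute_tomek(Xi, yi)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(cbind(got$index_a, got$index_b), unname(want))
    }
  }
})

test_that("SMOTE-Tomek balancing raises all classes to the majority count", {
  ft <- make_random_ft(n = 17, d = 3, seed = 2, counts = c(10, 5, 2))
  bal <- smote_tomek_balance(ft, smote_config(seed = 3))
  post <- table(factor(bal$y, levels = 0:2))
  # post-SMOTE counts are (10, 10, 10); with equal counts the larger-class
  # removal rule ties on every link, so nothing is removed
  expect_equal(as.integer(post), c(10, 10, 10))
  expect_equal(attr(bal, "n_removed"), 0L)
  # already balanced, well-separated classes -> identity
  sep <- make_separated_ft(5)
  bal2 <- smote_tomek_balance(sep, smote_config(seed = 1))
  expect_identical(bal2$X, sep$X)
  expect_identical(bal2$y, sep$y)
  # composed reference run: SMOTE sub-operation + link scan by hand
  ft30 <- make_random_ft(n = 30, d = 4, seed = 5, counts = c(14, 10, 6))
  bal3 <- smote_tomek_balance(ft30, smote_config(seed = 3))
  ref_X <- ft30$X; ref_y <- ft30$y
  for (cls in 0:2) {
    need <- 14 - sum(ft30$y == cls)
    if (need > 0) {
      syn <- smote_oversample(ft30$X[ft30$y == cls, , drop = FALSE], need,
                              smote_config(seed = 3 + cls))
      ref_X <- rbind(ref_X, syn); ref_y <- c(ref_y, rep(cls, need))
    }
  }
  # equal counts post-SMOTE: the larger-count rule ties everywhere, so the
  # reference output is the augmented table unchanged
  expect_equal(nrow(bal3$X), nrow(ref_X))
  expect_equal(unname(bal3$X), unname(ref_X))
})

test_that("post-balance class ratio never exceeds the post-SMOTE ratio", {
  for (seed in 1:5) {
    ft <- make_random_ft(n = 24, d = 3, seed = seed, counts = c(12, 8, 4))
    bal <- smote_tomek_balance(ft, smote_config(seed = seed))
    cnt <- as.integer(table(factor(bal$y, levels = 0:2)))
    expect_lte(max(cnt) / min(cnt), 1)  # post-SMOTE ratio is exactly 1
  }
})

test_that("stratified bootstrap preserves per-class counts exactly", {
  ft <- make_random_ft(n = 30, d = 3, seed = 4, counts = c(15, 10, 5))
  bs <- stratified_bootstrap(ft, seed = 8)
  expect_equal(table(factor(bs$y, levels = 0:2)),
               table(factor(ft$y, levels = 0:2)))
  expect_equal(nrow(bs$X), nrow(ft$X))
  expect_identical(stratified_bootstrap(ft, seed = 8)$X, bs$X)
  # one row per class -> identity
  ft3 <- feature_table(diag(3), 0:2)
  bs3 <- stratified_bootstrap(ft3, seed = 1)
  expect_identical(bs3$X, ft3$X)
})

test_that("bootstrap unique fraction matches 1 - (1 - 1/n)^n", {
  n <- 100
  ft <- feature_table(
    cbind(x = c(seq_len(n), seq_len(n) + 1000, seq_len(n) + 2000)),
    rep(0:2, each = n))
  fracs <- vapply(1:200, function(s) {
    bs <- stratified_bootstrap(ft, seed = s)
    length(unique(bs$X[bs$y == 0, 1])) / n
  }, numeric(1))
  expect_gte(mean(fracs), 0.60)
  expect_lte(mean(fracs), 0.67)
})
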