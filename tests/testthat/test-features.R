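test_that("cyclical month encoding follows the January-phase-zero convention", {
  enc <- encode_month_cyclical(c(1, 4, 7))
  expect_equal(enc[1, ], c(month_sin = 0, month_cos = 1))
  expect_equal(enc[2, ], c(month_sin = 1, month_cos = 0))
  expect_equal(enc[3, ], c(month_sin = 0, month_cos = -1))
  all12 <- encode_month_cyclical(1:12)
  expect_equal(rowSums(all12^2), rep(1, 12), tolerance = 1e-12)
  expect_true(all(all12 >= -1 & all12 <= 1))
  expect_error(encode_month_cyclical(0), "1..12")
  expect_error(encode_month_cyclical(13), "1..12")
})

test_that("shelf-life bins use strict outer and closed inner boundaries", {
  expect_equal(as.character(bin_shelf_life(c(3, 12, 24))),
               c("short", "medium", "long"))
  expect_equal(as.character(bin_shelf_life(c(5.999, 6, 18, 18.001))),
               c("short", "medium", "medium", "long"))
  expect_error(bin_shelf_life(0), "positive")
})

test_that("one-hot encoding respects category order and unknown policy", {
  M <- one_hot_encode(c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(M), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(colnames(M), c("a", "b"))
  expect_equal(unname(one_hot_encode(rep("x", 3), "x")),
               matrix(1, 3, 1))
  expect_error(one_hot_encode(c("a", "c"), c("a", "b")), "c")
  expect_warning(Z <- one_hot_encode(c("a", "c"), c("a", "b"), "ignore"),
                 "all-zero")
  expect_equal(unname(Z[2, ]), c(0, 0))
})

test_that("zero-variance filter keeps exactly the varying columns", {
  X <- cbind(a = c(0, 0, 0), b = c(1, 2, 3), c = c(5, 5, 6))
  out <- drop_zero_variance(X)
  expect_equal(out$kept, c("b", "c"))
  expect_equal(out$X, X[, c("b", "c")])
  # oracle: per-column distinct count
  expect_equal(out$kept,
               colnames(X)[apply(X, 2, function(v) length(unique(v))) > 1])
  X2 <- cbind(a = 1:3, b = c(2, 1, 7))
  expect_equal(drop_zero_variance(X2)$X, X2)
  expect_error(drop_zero_variance(cbind(a = rep(1, 3))), "constant")
})

test_that("feature matrix matches a hand-encoded fixture cell by cell", {
  rec <- data.frame(
    food_category = c("a", "b", "a", "b", "a"),
    cross_province = c("p", "q", "p", "q", "q"),
    sampling_site = "s1",                      # constant: filtered out
    sampling_province = c("z1", "z2", "z1", "z2", "z1"),
    package = c("u", "u", "v", "v", "u"),
    production_month = c(1, 4, 7, 10, 1),
    shelf_life_months = c(3, 12, 24, 6, 18),
    storage_condition = c("amb", "ref", "amb", "ref", "amb"),
    risk_class = c(0, 1, 2, 1, 0))
  fit <- build_feature_matrix(rec, feature_schema(categories = list()),
                              fit = TRUE)
  X <- fit$features$X
  hand <- cbind(
    "food_category=a" = c(1, 0, 1, 0, 1),
    "food_category=b" = c(0, 1, 0, 1, 0),
    "cross_province=p" = c(1, 0, 1, 0, 0),
    "cross_province=q" = c(0, 1, 0, 1, 1),
    "sampling_province=z1" = c(1, 0, 1, 0, 1),
    "sampling_province=z2" = c(0, 1, 0, 1, 0),
    "package=u" = c(1, 1, 0, 0, 1),
    "package=v" = c(0, 0, 1, 1, 0),
    month_sin = sin(2 * pi * (c(1, 4, 7, 10, 1) - 1) / 12),
    month_cos = cos(2 * pi * (c(1, 4, 7, 10, 1) - 1) / 12),
    "shelf_life=short" = c(1, 0, 0, 0, 0),
    "shelf_life=medium" = c(0, 1, 0, 1, 1),
    "shelf_life=long" = c(0, 0, 1, 0, 0),
    "storage_condition=amb" = c(1, 0, 1, 0, 1),
    "storage_condition=ref" = c(0, 1, 0, 1, 0))
  expect_equal(X, hand)
  expect_equal(fit$features$y, c(0L, 1L, 2L, 1L, 0L))
  # constant blocks (sampling_site, all-ones one-hot) must be gone
  expect_false(any(grepl("sampling_site", colnames(X))))
})

test_that("fitted schema replays identically and rejects unfitted transform", {
  tab <- generate_inspection_records(generator_config(150, seed = 3))
  fit <- build_feature_matrix(tab, feature_schema(), fit = TRUE)
  again <- build_feature_matrix(tab, fit$schema, fit = FALSE)
  expect_identical(fit$features$X, again$X)
  expect_identical(colnames(again$X), fit$schema$kept_columns)
  expect_error(build_feature_matrix(tab, feature_schema(), fit = FALSE),
               "not been fitted")
  # transform keeps fit-time columns even when test data lacks levels
  sub <- tab[tab$storage_condition == tab$storage_condition[1], ]
  tr <- build_feature_matrix(sub, fit$schema, fit = FALSE)
  expect_identical(colnames(tr$X), fit$schema$kept_columns)
  # one-hot blocks row-sum to 1 before filtering (raw encoding property)
  raw <- riskstack:::encode_design(tab, fit$schema, policy = "strict")
  for (field in c("food_category", "package", "storage_condition")) {
    block <- raw[, grepl(paste0("^", field, "="), colnames(raw)), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(tab)))
  }
})

test_that("schema JSON round-trip preserves the fitted transform", {
  tab <- generate_inspection_records(generator_config(80, seed = 8))
  fit <- build_feature_matrix(tab, feature_schema(), fit = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  schema_to_json(fit$schema, path)
  back <- schema_from_json(path)
  expect_identical(build_feature_matrix(tab, back, fit = FALSE)$X,
                   fit$features$X)
})
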