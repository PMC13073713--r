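# Feature engineering: cyclical month encoding, shelf-life binning, one-hot
# encoding and zero-variance filtering, composed into a fitted schema that is
# replayed unchanged at transform time.

#' Cyclical encoding of the production month
#'
#' Maps month m in 1..12 to `(sin(2*pi*(m-1)/12), cos(2*pi*(m-1)/12))`,
#' placing January at phase zero so the encoding wraps December onto January.
#'
#' @param month Integer vector with values in 1..12.
#' @return A numeric matrix with columns `month_sin` and `month_cos`.
#' @export
#' @examples
#' encode_month_cyclical(c(1, 4, 7))
encode_month_cyclical <- function(month) {
  if (length(month) == 0 || anyNA(month) || !all(month %in% 1:12))
    stop("month must contain integers in 1..12")
  angle <- 2 * pi * (month - 1) / 12
  cbind(month_sin = sin(angle), month_cos = cos(angle))
}

#' Bin shelf life into short / medium / long
#'
#' Short is strictly less than 6 months, medium is the closed interval
#' 6 to 18 months, long is strictly greater than 18 months.
#'
#' @param months Positive numeric vector of shelf lives in months.
#' @return Factor with levels `short`, `medium`, `long`.
#' @export
bin_shelf_life <- function(months) {
  if (length(months) == 0 || anyNA(months) || any(months <= 0))
    stop("shelf life must be strictly positive")
  out <- ifelse(months < 6, "short", ifelse(months <= 18, "medium", "long"))
  factor(out, levels = c("short", "medium", "long"))
}

#' One-hot encode a categorical vector against a fixed category list
#'
#' @param values Character (or factor) vector.
#' @param categories Ordered, duplicate-free category list defining the
#'   columns.
#' @param policy `"strict"` errors on a value absent from `categories`;
#'   `"ignore"` emits an all-zero row for it (with a warning).
#' @return Binary matrix with one column per category, in list order.
#' @export
one_hot_encode <- function(values, categories, policy = c("strict", "ignore")) {
  policy <- match.arg(policy)
  if (length(categories) == 0 || anyDuplicated(categories))
    stop("categories must be non-empty and duplicate-free")
  values <- as.character(values)
  unseen <- setdiff(unique(values), categories)
  if (length(unseen) > 0) {
    if (policy == "strict")
      stop("unseen categorical value(s): ", paste(unseen, collapse = ", "))
    warning("unseen categorical value(s) encoded as all-zero rows: ",
            paste(unseen, collapse = ", "))
  }
  M <- matrix(0, nrow = length(values), ncol = length(categories),
              dimnames = list(NULL, categories))
  hit <- match(values, categories)
  ok <- which(!is.na(hit))
  M[cbind(ok, hit[ok])] <- 1
  M
}

#' Drop zero-variance columns
#'
#' Keeps exactly the columns with more than one distinct value, preserving
#' the original order, and returns the kept names for test-time replay.
#'
#' @param X Numeric matrix with column names.
#' @param column_names Optional explicit column names (defaults to
#'   `colnames(X)`).
#' @return List with `X` (filtered matrix) and `kept` (ordered name list).
#' @export
drop_zero_variance <- function(X, column_names = colnames(X)) {
  if (is.null(dim(X)) || nrow(X) == 0 || ncol(X) == 0)
    stop("X must be a non-empty matrix")
  distinct <- apply(X, 2, function(col) length(unique(col)))
  keep <- which(distinct > 1)
  if (length(keep) == 0)
    stop("all columns are constant; degenerate design matrix")
  list(X = X[, keep, drop = FALSE], kept = column_names[keep])
}

#' Feature schema
#'
#' Holds the categorical level lists, the month-encoding convention, the
#' shelf-life bin edges and (once fitted) the zero-variance-filtered column
#' list, so that transform-time encoding replays the training-time layout
#' exactly.
#'
#' @param categories Named list of ordered category vectors for the fields
#'   `food_category`, `cross_province`, `sampling_site`, `sampling_province`,
#'   `package` and `storage_condition`. Fields left `NULL` are filled from
#'   the data at fit time (sorted unique values).
#' @param shelf_bins Strictly increasing bin edges for shelf life (months).
#' @param unknown_policy Transform-time policy for unseen category values.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(categories = generator_levels(),
                           shelf_bins = c(6, 18),
                           unknown_policy = c("ignore", "strict")) {
  unknown_policy <- match.arg(unknown_policy)
  if (is.unsorted(shelf_bins, strictly = TRUE))
    stop("shelf_bins must be strictly increasing")
  for (nm in names(categories)) {
    cl <- categories[[nm]]
    if (!is.null(cl) && (length(cl) == 0 || anyDuplicated(cl)))
      stop("category list for ", nm, " must be non-empty and duplicate-free")
  }
  structure(list(categories = categories,
                 month_convention = "january_phase_zero",
                 shelf_bins = as.numeric(shelf_bins),
                 unknown_policy = unknown_policy,
                 kept_columns = NULL),
            class = "feature_schema")
}

categorical_fields <- function() {
  c("food_category", "cross_province", "sampling_site", "sampling_province",
    "package")
}

# Raw (pre-filter) encoded design matrix in the documented column order.
encode_design <- function(records, schema, policy) {
  blocks <- list()
  for (field in categorical_fields()) {
    cats <- schema$categories[[field]] %||%
      sort(unique(as.character(records[[field]])))
    B <- one_hot_encode(records[[field]], cats, policy = policy)
    colnames(B) <- paste(field, cats, sep = "=")
    blocks[[field]] <- B
  }
  blocks[["month"]] <- encode_month_cyclical(records$production_month)
  shelf_cats <- c("short", "medium", "long")
  S <- one_hot_encode(as.character(bin_shelf_life(records$shelf_life_months)),
                      shelf_cats, policy = "strict")
  colnames(S) <- paste("shelf_life", shelf_cats, sep = "=")
  blocks[["shelf"]] <- S
  stor_cats <- schema$categories[["storage_condition"]] %||%
    sort(unique(as.character(records$storage_condition)))
  ST <- one_hot_encode(records$storage_condition, stor_cats, policy = policy)
  colnames(ST) <- paste("storage_condition", stor_cats, sep = "=")
  blocks[["storage"]] <- ST
  do.call(cbind, unname(blocks))
}

#' Build the numeric feature matrix from a record table
#'
#' Concatenates, in order: one-hot food category, cross-province status,
#' sampling site, sampling province, package; cyclical month sine/cosine;
#' one-hot shelf-life bin; one-hot storage condition. At fit time
#' (`fit = TRUE`) a zero-variance filter is fitted on the encoded matrix and
#' stored in the schema; at transform time the fitted column list is
#' replayed without refitting.
#'
#' @param records A record table (labels optional at transform time).
#' @param schema A [feature_schema()]. Must be fitted when `fit = FALSE`.
#' @param fit Whether to fit the schema (category completion + zero-variance
#'   filter) on these records.
#' @return When `fit = TRUE`, a list with `features` (a `feature_table`) and
#'   the fitted `schema`; otherwise just the `feature_table` — a list with
#'   elements `X` (numeric matrix), `y` (integer labels or `NULL`) and
#'   `column_names`.
#' @export
build_feature_matrix <- function(records, schema = feature_schema(),
                                 fit = TRUE) {
  stopifnot(inherits(schema, "feature_schema"))
  records <- validate_records(records)
  if (fit) {
    for (field in c(categorical_fields(), "storage_condition")) {
      if (is.null(schema$categories[[field]]))
        schema$categories[[field]] <-
          sort(unique(as.character(records[[field]])))
    }
    X <- encode_design(records, schema, policy = "strict")
    filt <- drop_zero_variance(X)
    schema$kept_columns <- filt$kept
    ft <- feature_table(filt$X, records$risk_class)
    return(list(features = ft, schema = schema))
  }
  if (is.null(schema$kept_columns))
    stop("schema has not been fitted; call build_feature_matrix(fit = TRUE) first")
  X <- encode_design(records, schema, policy = schema$unknown_policy)
  X <- X[, schema$kept_columns, drop = FALSE]
  feature_table(X, records$risk_class)
}

#' Feature table constructor
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Optional integer label vector in {0,1,2}, aligned with `X` rows.
#' @return An object of class `feature_table` with elements `X`, `y`,
#'   `column_names`.
#' @export
feature_table <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("feature matrix must have no missing values")
  if (anyDuplicated(colnames(X))) stop("column names must be unique")
  if (!is.null(y)) {
    y <- check_labels(y)
    if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  }
  structure(list(X = X, y = y, column_names = colnames(X)),
            class = "feature_table")
}

#' Serialize / deserialize a fitted feature schema as JSON
#'
#' @param schema A fitted [feature_schema()].
#' @param path JSON file path.
#' @return `schema_to_json()` returns `path` invisibly; `schema_from_json()`
#'   returns the schema.
#' @export
schema_to_json <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(unclass(schema), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname schema_to_json
#' @export
schema_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sch <- feature_schema(categories = as.list(raw$categories),
                        shelf_bins = raw$shelf_bins,
                        unknown_policy = raw$unknown_policy)
  sch$kept_columns <- raw$kept_columns
  sch
}
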