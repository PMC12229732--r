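#' Extract a (standardized) numeric feature matrix
#'
#' Selects numeric columns from a record table in the requested order and
#' optionally z-scores each column, recording the centering and scaling
#' parameters so the transformation is exactly invertible. Standardization
#' divides by the population standard deviation (divisor `n`) by default;
#' set `scale_type = "sample"` for the `n - 1` convention. Columns that are
#' constant get scale 1 and become all zeros rather than `NaN`.
#'
#' Rows with a missing value in any requested feature are dropped with a
#' message (the detectors assume complete rows; no imputation is attempted).
#'
#' @param table A record-table tibble.
#' @param features Character vector of numeric column names, default the ten
#'   agronomic measurements from [agri_feature_names()].
#' @param standardize Logical; z-score each column (default `TRUE`).
#' @param scale_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @return A `feature_matrix` object: a list with `values` (n x d numeric
#'   matrix), `feature_names`, `center`, `scale`, `row_ids` and the
#'   standardization settings.
#' @export
#' @examples
#' fm <- extract_features(table1_fixture(), c("n", "p", "k", "ph", "ec"))
#' colMeans(fm$values)
extract_features <- function(table, features = agri_feature_names(),
                             standardize = TRUE,
                             scale_type = c("population", "sample")) {
  scale_type <- match.arg(scale_type)
  missing_cols <- setdiff(features, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("feature(s) not in table: ",
                 paste(missing_cols, collapse = ", ")),
          class = "agri_schema_error")
  }
  non_num <- features[!vapply(table[features], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("feature(s) not numeric: ", paste(non_num, collapse = ", ")),
          class = "agri_type_error")
  }

  row_ids <- if ("row_id" %in% names(table)) table$row_id else seq_len(nrow(table))
  values <- as.matrix(table[, features, drop = FALSE])
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    message(sum(!complete), " row(s) with missing feature values dropped")
    values <- values[complete, , drop = FALSE]
    row_ids <- row_ids[complete]
  }
  if (nrow(values) < 2) {
    abort("need at least 2 complete rows to build a feature matrix",
          class = "agri_size_error")
  }

  if (standardize) {
    center <- colMeans(values)
    centered <- sweep(values, 2, center, "-")
    scl <- if (scale_type == "population") {
      sqrt(colMeans(centered^2))
    } else {
      apply(values, 2, sd)
    }
    scl[scl == 0] <- 1
    values <- sweep(centered, 2, scl, "/")
  } else {
    center <- rep(0, ncol(values))
    scl <- rep(1, ncol(values))
  }
  names(center) <- names(scl) <- features
  dimnames(values) <- list(NULL, features)

  structure(
    list(values = values, feature_names = features, center = center,
         scale = scl, row_ids = row_ids, standardized = standardize,
         scale_type = scale_type),
    class = "feature_matrix"
  )
}

#' Coerce to a feature matrix
#'
#' Detectors accept either a record-table tibble (features are extracted with
#' the given settings) or an existing `feature_matrix`, which passes through
#' unchanged.
#'
#' @param x A record-table tibble, plain data frame or `feature_matrix`.
#' @param features,standardize,scale_type Passed to [extract_features()]
#'   when `x` is a table; `features = NULL` selects the default agronomic
#'   set when present, otherwise all numeric columns except `row_id`.
#' @return A `feature_matrix`.
#' @export
as_feature_matrix <- function(x, features = NULL, standardize = TRUE,
                              scale_type = "population") {
  if (inherits(x, "feature_matrix")) {
    return(x)
  }
  if (is.matrix(x)) {
    x <- tibble::as_tibble(x, .name_repair = "unique")
  }
  if (!is.data.frame(x)) {
    abort("cannot interpret input as a feature matrix",
          class = "agri_type_error")
  }
  if (is.null(features)) {
    default <- intersect(agri_feature_names(), names(x))
    features <- if (length(default) > 0) {
      default
    } else {
      setdiff(names(x)[vapply(x, is.numeric, logical(1))], "row_id")
    }
  }
  extract_features(x, features, standardize = standardize,
                   scale_type = scale_type)
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " rows x ", ncol(x$values),
      " features (", if (x$standardized) paste0("standardized, ", x$scale_type, " sd")
      else "raw", ")\n", sep = "")
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

# invert standardization: values * scale + center
destandardize <- function(fm) {
  sweep(sweep(fm$values, 2, fm$scale, "*"), 2, fm$center, "+")
}
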