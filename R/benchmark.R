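#' Confusion matrix for outlier detection
#'
#' The positive class is "outlier" throughout the package: `tp` counts true
#' outliers flagged, `fp` inliers flagged, `fn` outliers missed, `tn`
#' inliers passed.
#'
#' @param truth,predicted Equal-length logical vectors (ground truth and
#'   detector flags).
#' @return A one-row `confusion_matrix` tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_from_labels(c(TRUE, TRUE, FALSE, FALSE),
#'                       c(TRUE, FALSE, TRUE, FALSE))
confusion_from_labels <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted must have equal length",
          class = "agri_alignment_error")
  }
  if (length(truth) < 1) {
    abort("need at least one observation", class = "agri_size_error")
  }
  truth <- as.logical(truth)
  predicted <- as.logical(predicted)
  out <- tibble::tibble(
    tp = sum(truth & predicted),
    fp = sum(!truth & predicted),
    fn = sum(truth & !predicted),
    tn = sum(!truth & !predicted)
  )
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Harmonic mean of precision and recall
#'
#' `f1 = 2 * precision * recall / (precision + recall)`, with 0 when both
#' are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return The F1 score.
#' @export
#' @examples
#' f1_score(0.8925, 0.9891)
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision / recall / F1 / accuracy from a confusion matrix
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, `f1` their
#' harmonic mean, `accuracy = (tp + tn) / n`. Zero-denominator cases (no
#' flagged rows, or no true outliers) return 0 for the affected metric with
#' `degenerate = TRUE` rather than raising, so benchmark tables never abort.
#'
#' @param cm A `confusion_matrix` (or any one-row data frame with `tp`,
#'   `fp`, `fn`, `tn`).
#' @param method Optional method name carried into the row.
#' @return A one-row tibble: `method`, `precision`, `recall`, `f1`,
#'   `accuracy`, `degenerate`.
#' @export
#' @examples
#' metrics_from_confusion(confusion_from_labels(c(TRUE, FALSE), c(TRUE, FALSE)))
metrics_from_confusion <- function(cm, method = NA_character_) {
  tp <- cm$tp[1]; fp <- cm$fp[1]; fn <- cm$fn[1]; tn <- cm$tn[1]
  n <- tp + fp + fn + tn
  degenerate <- FALSE
  precision <- if (tp + fp == 0) {
    degenerate <- TRUE
    0
  } else {
    tp / (tp + fp)
  }
  recall <- if (tp + fn == 0) {
    degenerate <- TRUE
    0
  } else {
    tp / (tp + fn)
  }
  tibble::tibble(
    method = method,
    precision = precision, recall = recall,
    f1 = f1_score(precision, recall),
    accuracy = (tp + tn) / n,
    degenerate = degenerate
  )
}

#' Default benchmark configurations for the six detectors
#'
#' One configuration per benchmarked algorithm: elliptic (Mahalanobis)
#' envelope, isolation forest, one-class SVM, iterative IQR, SVD residual
#' and SMVOD. The PCA + Euclidean envelope variant can be added as an extra
#' entry (`pca_envelope = list(n_components = 0.95, percentile = 95)`).
#'
#' @param contamination Assumed contamination passed to the quantile-based
#'   thresholds (default 0.05, matching the default synthetic spec).
#' @param seed Integer seed for the stochastic methods.
#' @return Named list of per-method parameter lists, one per detector.
#' @export
default_method_configs <- function(contamination = 0.05, seed = 1) {
  pct <- 100 * (1 - contamination)
  list(
    mahalanobis_envelope = list(confidence = 0.95),
    isolation_forest = list(n_trees = 100, subsample = 256,
                            contamination = contamination, seed = seed),
    one_class_svm = list(nu = contamination, kernel = "rbf", gamma = "auto"),
    iterative_iqr = list(k = 1.5, max_iterations = 100),
    ssvd_residual = list(rank = 0.90, percentile = pct),
    smvod = list(sigma = "auto", alpha_mix = 0.5, percentile = pct)
  )
}

# method name -> function(data, features, coords, params) -> outlier_result
benchmark_dispatch <- function(name, data, features, coords, params) {
  switch(
    name,
    iterative_iqr = do.call(detect_iterative_iqr,
                            c(list(data = data, features = features), params)),
    mahalanobis_envelope = do.call(detect_mahalanobis_envelope,
                                   c(list(data = data, features = features), params)),
    pca_envelope = do.call(detect_pca_envelope,
                           c(list(data = data, features = features), params)),
    isolation_forest = do.call(detect_isolation_forest,
                               c(list(data = data, features = features), params)),
    one_class_svm = do.call(detect_ocsvm,
                            c(list(data = data, features = features), params)),
    ssvd_residual = do.call(detect_ssvd_residual,
                            c(list(data = data, features = features), params)),
    smvod = do.call(detect_smvod,
                    c(list(data = data, features = features, coords = coords),
                      params)),
    abort(paste0("unknown method: ", name), class = "agri_config_error")
  )
}

#' Run the detector benchmark on a labeled dataset
#'
#' Runs every configured detector on the dataset's feature matrix (plus
#' coordinates for the spatial methods) and evaluates each against the
#' ground-truth outlier flags. A detector failure is recorded as a failed
#' row (`error` column) and the remaining methods still run. Unlabeled
#' input is refused: the benchmark never invents ground truth.
#'
#' @param dataset A `labeled_dataset` (from [generate_dataset()] or
#'   [read_labeled_dataset()]).
#' @param methods Named list of per-method parameter lists; see
#'   [default_method_configs()] for the six defaults.
#' @param features Feature columns (default: the agronomic feature set
#'   present in the table, otherwise all numeric non-coordinate columns).
#' @return A `benchmark_report`: list with `metrics` (one row per method:
#'   confusion counts plus precision/recall/F1/accuracy), `dataset_summary`
#'   and `configs`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_inliers = 190, contamination = 0.05,
#'                                       seed = 7))
#' rep <- run_benchmark(ds)
#' tidy(rep)
run_benchmark <- function(dataset, methods = default_method_configs(),
                          features = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(dataset$labels) || !"is_outlier" %in% names(dataset$labels)) {
    abort("dataset has no ground-truth labels; the benchmark refuses unlabeled input",
          class = "agri_config_error")
  }
  known <- c("iterative_iqr", "mahalanobis_envelope", "pca_envelope",
             "isolation_forest", "one_class_svm", "ssvd_residual", "smvod")
  unknown <- setdiff(names(methods), known)
  if (length(unknown) > 0 || is.null(names(methods))) {
    abort(paste0("unknown method: ", paste(unknown, collapse = ", ")),
          class = "agri_config_error")
  }
  tab <- dataset$table
  if (is.null(features)) {
    features <- intersect(agri_feature_names(), names(tab))
    if (length(features) == 0) {
      features <- setdiff(
        names(tab)[vapply(tab, is.numeric, logical(1))],
        c("row_id", "latitude", "longitude")
      )
    }
  }
  coords <- if (all(c("latitude", "longitude") %in% names(tab))) {
    tab[, c("latitude", "longitude")]
  } else {
    NULL
  }
  truth <- dataset$labels$is_outlier

  rows <- purrr::imap(methods, function(params, name) {
    res <- tryCatch(
      benchmark_dispatch(name, tab, features, coords, params),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      return(tibble::tibble(
        method = name, tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
        tn = NA_integer_, precision = NA_real_, recall = NA_real_,
        f1 = NA_real_, accuracy = NA_real_, degenerate = NA,
        n_flagged = NA_integer_, error = conditionMessage(res)
      ))
    }
    cm <- confusion_from_labels(truth, res$flags)
    met <- metrics_from_confusion(cm, method = name)
    dplyr::bind_cols(met[, "method"], cm, met[, -1],
                     tibble::tibble(n_flagged = res$n_flagged,
                                    error = NA_character_))
  })

  spec <- dataset$spec
  summary <- list(
    n = nrow(tab),
    n_outliers = sum(truth),
    contamination = if (!is.null(spec)) spec$contamination else mean(truth),
    outlier_mix = if (!is.null(spec)) as.list(spec$outlier_mix) else NULL,
    seed = if (!is.null(spec)) spec$seed else NULL,
    features = features
  )
  structure(
    list(metrics = dplyr::bind_rows(rows), dataset_summary = summary,
         configs = methods),
    class = "benchmark_report"
  )
}

#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) x$metrics

#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(
    n = x$dataset_summary$n,
    n_outliers = x$dataset_summary$n_outliers,
    n_methods = nrow(x$metrics),
    n_failed = sum(!is.na(x$metrics$error)),
    best_f1_method = x$metrics$method[which.max(x$metrics$f1)],
    best_f1 = max(x$metrics$f1, na.rm = TRUE)
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> n =", x$dataset_summary$n, "rows,",
      x$dataset_summary$n_outliers, "true outliers\n\n")
  m <- x$metrics
  out <- data.frame(
    method = m$method,
    precision = sprintf("%.4f", m$precision),
    recall = sprintf("%.4f", m$recall),
    f1 = sprintf("%.4f", m$f1),
    accuracy = sprintf("%.4f", m$accuracy)
  )
  out[is.na(m$precision), -1] <- "--"
  print(out, row.names = FALSE)
  if (any(!is.na(m$error))) {
    cat("\nfailed:", paste(m$method[!is.na(m$error)], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize / restore a benchmark report
#'
#' JSON round trip: `write_benchmark_report()` followed by
#' `read_benchmark_report()` reproduces the metrics table, dataset summary
#' and configs.
#'
#' @param report A `benchmark_report`.
#' @param path JSON file path.
#' @return `path` invisibly; the reader returns a `benchmark_report`.
#' @export
write_benchmark_report <- function(report, path) {
  jsonlite::write_json(
    list(metrics = report$metrics,
         dataset_summary = report$dataset_summary,
         configs = report$configs),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_benchmark_report
#' @export
read_benchmark_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  metrics <- tibble::as_tibble(obj$metrics)
  if (!"error" %in% names(metrics)) {
    metrics$error <- NA_character_
  }
  structure(
    list(metrics = metrics, dataset_summary = obj$dataset_summary,
         configs = obj$configs),
    class = "benchmark_report"
  )
}

#' Bar chart of benchmark metrics per method
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$metrics[, c("method", "precision", "recall", "f1", "accuracy")],
    -"method", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Outlier-detection benchmark") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
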