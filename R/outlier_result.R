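#' Construct an outlier-detection result
#'
#' Common contract shared by all detectors: a per-row anomaly score (higher
#' means more anomalous), a threshold, and flags obtained by strict
#' exceedance (`score > threshold`; ties are inliers, uniformly across
#' methods so flagged fractions are comparable).
#'
#' @param scores Numeric vector of finite anomaly scores.
#' @param threshold Scalar decision threshold.
#' @param method Method name.
#' @param params Named list of the parameters the method actually used.
#' @param row_ids Row identifiers aligned with `scores`.
#' @return An `outlier_result` object.
#' @keywords internal
new_outlier_result <- function(scores, threshold, method, params,
                               row_ids = seq_along(scores)) {
  stopifnot(is.numeric(scores), length(threshold) == 1L)
  if (any(!is.finite(scores))) {
    abort(paste0(method, ": non-finite anomaly score produced"),
          class = "agri_numeric_error")
  }
  flags <- scores > threshold
  structure(
    list(scores = as.numeric(scores), flags = flags,
         threshold = as.numeric(threshold), method = method,
         params = params, row_ids = row_ids, n_flagged = sum(flags)),
    class = "outlier_result"
  )
}

#' @export
print.outlier_result <- function(x, ...) {
  cat("<outlier_result> method:", x$method, "\n")
  cat("  n =", length(x$scores), " flagged =", x$n_flagged,
      " threshold =", format(x$threshold, digits = 6), "\n")
  invisible(x)
}

#' Tidy an outlier result into a per-row tibble
#'
#' @param x An `outlier_result`.
#' @param ... Unused.
#' @return A tibble with `row_id`, `score`, `flagged`.
#' @method tidy outlier_result
#' @export
tidy.outlier_result <- function(x, ...) {
  tibble::tibble(row_id = x$row_ids, score = x$scores, flagged = x$flags)
}

#' One-row summary of an outlier result
#'
#' @param x An `outlier_result`.
#' @param ... Unused.
#' @return A one-row tibble with method, n, n_flagged, flagged fraction and
#'   threshold.
#' @method glance outlier_result
#' @export
glance.outlier_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = length(x$scores), n_flagged = x$n_flagged,
    frac_flagged = x$n_flagged / length(x$scores), threshold = x$threshold
  )
}

#' Score histogram with decision threshold
#'
#' @param object An `outlier_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot outlier_result
#' @export
autoplot.outlier_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$flagged)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.85) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "#d1495b")) +
    ggplot2::labs(title = paste0(object$method, ": anomaly scores"),
                  x = "score", y = "count", fill = "flagged") +
    ggplot2::theme_minimal()
}

# strict-exceedance threshold at the q-th percentile (type-7 interpolation)
percentile_threshold <- function(scores, percentile) {
  if (percentile <= 0 || percentile >= 100) {
    abort("percentile must be strictly between 0 and 100",
          class = "agri_value_error")
  }
  unname(quantile(scores, percentile / 100, type = 7, names = FALSE))
}
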