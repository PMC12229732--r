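#' One-class support vector machine
#'
#' Separates the data from the origin in (kernel) feature space with the
#' largest margin, trading margin against slack through the parameter `nu`,
#' which upper-bounds the fraction of training points outside the boundary
#' and lower-bounds the fraction of support vectors. The convex
#' nu-parameterized dual (box constraints `[0, 1/(nu * n)]`, weights summing
#' to 1) is solved by the libsvm optimizer via \pkg{e1071}; the contract
#' here is the dual solution and decision function, not the solver.
#'
#' The decision value is `g(x) = sum_i alpha_i K(x_i, x) - rho`; the anomaly
#' score is `-g(x)` with threshold 0, so rows with `g(x) < 0` (outside the
#' learned boundary) are flagged.
#'
#' @param data A record-table tibble or `feature_matrix` (standardized by
#'   default when a table is given; the RBF kernel is scale-sensitive).
#' @param features Feature columns when `data` is a table.
#' @param nu Trade-off parameter in (0, 1], default 0.1 (the assumed
#'   contamination).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width; `"auto"` (default) uses `1 / (d * var(x))`, the
#'   pooled-variance heuristic.
#' @return An `outlier_result`; `params` records `rho` and the normalized
#'   dual weights (support-vector coefficients divided by `nu * n`, which
#'   lie in `[0, 1/(nu * n)]` and sum to 1).
#' @export
#' @examples
#' fm <- extract_features(table1_fixture(), c("n", "p", "k", "ph", "ec"))
#' glance(detect_ocsvm(fm, nu = 0.1))
detect_ocsvm <- function(data, features = NULL, nu = 0.1,
                         kernel = c("rbf", "linear"), gamma = "auto") {
  kernel <- match.arg(kernel)
  if (nu <= 0 || nu > 1) {
    abort("nu must be in (0, 1]", class = "agri_value_error")
  }
  fm <- as_feature_matrix(data, features, standardize = TRUE)
  x <- fm$values
  n <- nrow(x)
  if (n < 2) {
    abort("one-class SVM needs at least 2 rows", class = "agri_size_error")
  }
  if (identical(gamma, "auto")) {
    v <- stats::var(as.vector(x))
    gamma <- 1 / (ncol(x) * ifelse(v > 0, v, 1))
  }

  model <- e1071::svm(
    x, y = NULL, type = "one-classification", scale = FALSE,
    kernel = if (kernel == "rbf") "radial" else "linear",
    gamma = gamma, nu = nu, tolerance = 1e-8
  )
  g <- attr(predict(model, x, decision.values = TRUE), "decision.values")
  g <- as.numeric(g)
  # free support vectors sit exactly on the boundary (g = 0) at the optimum;
  # snap solver rounding noise to 0 so ties stay inliers per the contract
  g[abs(g) < 1e-6 * max(abs(g))] <- 0

  dual <- numeric(n)
  dual[model$index] <- as.numeric(model$coefs) / (nu * n)

  new_outlier_result(
    scores = -g, threshold = 0, method = "one_class_svm",
    params = list(nu = nu, kernel = kernel, gamma = gamma,
                  rho = model$rho / (nu * n), dual_weights = dual,
                  n_support = model$tot.nSV),
    row_ids = fm$row_ids
  )
}
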