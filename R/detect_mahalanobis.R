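#' Mahalanobis elliptic envelope
#'
#' Fits a Gaussian envelope to the feature cloud: scores are squared
#' Mahalanobis distances \eqn{D^2_M(x) = (x - \mu)^\top \Sigma^{-1} (x - \mu)}
#' from the sample mean under the sample covariance, and the decision
#' boundary is the chi-square quantile with `d` degrees of freedom at the
#' requested confidence (under Gaussian data, \eqn{D^2_M \sim \chi^2_d}).
#' Rows strictly beyond the quantile are flagged.
#'
#' The covariance gets a small ridge (`1e-8 * mean(diag(Sigma))`) before
#' inversion. With `robust = TRUE` a one-step trimmed refit is used: mean
#' and covariance are re-estimated from the 50% of rows with the smallest
#' initial distances, which resists swamping by gross outliers.
#'
#' @param data A record-table tibble or `feature_matrix` (standardized by
#'   default when a table is given; Mahalanobis distance is affine
#'   invariant, so this only conditions the covariance numerically).
#' @param features Feature columns when `data` is a table.
#' @param confidence Envelope confidence level in (0, 1), default 0.95.
#' @param robust Use the trimmed refit (default `FALSE`, keeping the
#'   estimator simple and exactly checkable).
#' @return An `outlier_result` with squared-distance scores and the
#'   chi-square threshold; `params` records `mu` and `sigma`.
#' @export
#' @examples
#' res <- detect_mahalanobis_envelope(table1_fixture(),
#'                                    features = c("n", "p", "k", "ph", "ec"))
#' glance(res)
detect_mahalanobis_envelope <- function(data, features = NULL,
                                        confidence = 0.95, robust = FALSE) {
  if (confidence <= 0 || confidence >= 1) {
    abort("confidence must be in (0, 1)", class = "agri_value_error")
  }
  fm <- as_feature_matrix(data, features, standardize = TRUE)
  x <- fm$values
  n <- nrow(x)
  d <- ncol(x)
  if (n <= d) {
    abort("need more rows than features for a covariance envelope",
          class = "agri_size_error")
  }

  fit <- function(xs) {
    mu <- colMeans(xs)
    sigma <- cov(xs)
    sigma <- sigma + diag(1e-8 * mean(diag(sigma)), d)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev)) {
      abort(paste0("covariance singular after regularization (smallest eigenvalue ",
                   format(min(ev), digits = 4), ")"),
            class = "agri_numeric_error")
    }
    list(mu = mu, sigma = sigma)
  }

  est <- fit(x)
  if (robust) {
    d2 <- mahalanobis(x, est$mu, est$sigma)
    keep <- order(d2)[seq_len(max(d + 1, floor(n / 2)))]
    est <- fit(x[keep, , drop = FALSE])
  }
  scores <- mahalanobis(x, est$mu, est$sigma)

  new_outlier_result(
    scores = scores, threshold = qchisq(confidence, df = d),
    method = "mahalanobis_envelope",
    params = list(confidence = confidence, df = d, robust = robust,
                  mu = est$mu, sigma = est$sigma),
    row_ids = fm$row_ids
  )
}
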