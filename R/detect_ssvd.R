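#' Truncated-SVD reconstruction-residual detector
#'
#' Decomposes the column-centred feature matrix as `X ~ U D V'`, keeps the
#' top `rank` components, reconstructs `X_hat = U_r D_r V_r'` and scores
#' each row by the Euclidean norm of its residual row `X - X_hat`: records
#' poorly explained by the dominant low-rank structure are anomalous. The
#' threshold is the `percentile`-th percentile of the residual norms,
#' exceeded strictly. By the Eckart-Young theorem the squared Frobenius norm
#' of the residual equals the sum of squared discarded singular values.
#'
#' @param data A record-table tibble or `feature_matrix` (standardized by
#'   default when a table is given).
#' @param features Feature columns when `data` is a table.
#' @param rank Either an integer rank `r` with `1 <= r < min(n, d)`, or a
#'   fraction in (0, 1) interpreted as the minimum share of squared
#'   singular-value energy to retain (default 0.90). Requesting
#'   `r >= min(n, d)` is rejected: the residuals would be identically zero.
#' @param percentile Threshold percentile in (0, 100), default 95.
#' @return An `outlier_result` with residual-norm scores; `params` records
#'   the rank used and the singular values.
#' @export
#' @examples
#' fm <- extract_features(table1_fixture(), c("n", "p", "k", "ph", "ec"))
#' glance(detect_ssvd_residual(fm, rank = 2))
detect_ssvd_residual <- function(data, features = NULL, rank = 0.90,
                                 percentile = 95) {
  fm <- as_feature_matrix(data, features, standardize = TRUE)
  x <- fm$values
  n <- nrow(x)
  d <- ncol(x)
  if (n < 3) {
    abort("SVD residual detector needs at least 3 rows",
          class = "agri_size_error")
  }
  xc <- sweep(x, 2, colMeans(x), "-")
  sv <- svd(xc)
  if (sum(sv$d^2) == 0) { # all rows identical: zero residuals everywhere
    return(new_outlier_result(
      scores = rep(0, n), threshold = 0, method = "ssvd_residual",
      params = list(rank = 0, percentile = percentile,
                    singular_values = sv$d, energy_retained = 0),
      row_ids = fm$row_ids
    ))
  }
  energy <- sv$d^2 / sum(sv$d^2)

  if (length(rank) != 1 || rank <= 0) {
    abort("rank must be a positive count or an energy fraction in (0, 1)",
          class = "agri_value_error")
  }
  r <- if (rank < 1) {
    min(which(cumsum(energy) >= rank)[1], min(n, d) - 1L)
  } else {
    as.integer(rank)
  }
  if (r >= min(n, d)) {
    abort(paste0("rank must be < min(n, d) = ", min(n, d),
                 " (full rank leaves zero residuals)"),
          class = "agri_value_error")
  }

  recon <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
  scores <- sqrt(rowSums((xc - recon)^2))
  threshold <- percentile_threshold(scores, percentile)

  new_outlier_result(
    scores = scores, threshold = threshold, method = "ssvd_residual",
    params = list(rank = r, percentile = percentile,
                  singular_values = sv$d,
                  energy_retained = sum(energy[seq_len(r)])),
    row_ids = fm$row_ids
  )
}
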