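#' PCA + Euclidean-distance envelope
#'
#' The percentile-thresholded principal-component envelope: the centred
#' feature matrix is projected onto the top `p` principal components
#' (eigenvectors of the covariance matrix), each row is scored by its
#' Euclidean distance to the centre of the projected cloud, and the
#' threshold is the `percentile`-th percentile of those distances (default
#' the 95th, P95). Rows strictly beyond the threshold are flagged, so with
#' distinct distances and the default percentile exactly 5% of rows exceed
#' it. Unlike the Mahalanobis envelope this makes no elliptic assumption:
#' the PCA step captures the dominant variance and the isotropic distance
#' in component space tolerates non-Gaussian shapes.
#'
#' @param data A record-table tibble or `feature_matrix` (features are
#'   standardized by default when a table is given, so no single measurement
#'   unit dominates the distance).
#' @param features Feature columns when `data` is a table.
#' @param n_components Either an integer number of components `p`, or a
#'   fraction in (0, 1) interpreted as the minimum share of variance to
#'   retain (default 0.95: smallest `p` explaining at least 95% of
#'   variance).
#' @param percentile Threshold percentile in (0, 100), default 95
#'   (linear-interpolation/type-7 convention, recorded in `params`).
#' @return An `outlier_result` with distance scores; `params` records the
#'   number of components and the variance they explain.
#' @export
#' @examples
#' res <- detect_pca_envelope(table1_fixture(), features = c("n", "p", "k"))
#' glance(res)
detect_pca_envelope <- function(data, features = NULL, n_components = 0.95,
                                percentile = 95) {
  fm <- as_feature_matrix(data, features, standardize = TRUE)
  x <- fm$values
  n <- nrow(x)
  d <- ncol(x)
  if (n < 3) {
    abort("PCA envelope needs at least 3 rows", class = "agri_size_error")
  }

  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(pca$sdev^2) == 0) { # all rows identical: no variance, no outliers
    return(new_outlier_result(
      scores = rep(0, n), threshold = 0, method = "pca_envelope",
      params = list(n_components = 0, variance_explained = 0,
                    percentile = percentile, percentile_type = 7),
      row_ids = fm$row_ids
    ))
  }
  var_share <- pca$sdev^2 / sum(pca$sdev^2)
  if (length(n_components) != 1 || n_components <= 0) {
    abort("n_components must be a positive count or a variance fraction in (0, 1)",
          class = "agri_value_error")
  }
  p <- if (n_components < 1) {
    which(cumsum(var_share) >= n_components)[1]
  } else {
    as.integer(n_components)
  }
  if (is.na(p) || p > d) {
    abort(paste0("requested ", n_components, " components but only ", d,
                 " features"), class = "agri_value_error")
  }

  proj <- pca$x[, seq_len(p), drop = FALSE]
  center <- colMeans(proj) # ~0: projection of the centred data
  scores <- sqrt(rowSums(sweep(proj, 2, center, "-")^2))
  threshold <- percentile_threshold(scores, percentile)

  new_outlier_result(
    scores = scores, threshold = threshold, method = "pca_envelope",
    params = list(n_components = p,
                  variance_explained = sum(var_share[seq_len(p)]),
                  percentile = percentile, percentile_type = 7),
    row_ids = fm$row_ids
  )
}
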