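#' Spatial weight matrix from coordinates
#'
#' Gaussian kernel on pairwise geographic distances:
#' `W_s[i, j] = exp(-D[i, j]^2 / sigma^2)`, where `D` is the pairwise
#' distance between sample coordinates. Distances default to Euclidean on
#' decimal degrees (adequate for ranking within a sub-degree regional
#' extent); `distance = "greatcircle"` uses WGS84 great-circle kilometres.
#'
#' @param coords A data frame / tibble with `latitude` and `longitude`
#'   columns, or a two-column matrix (latitude, longitude).
#' @param sigma Positive bandwidth in distance units, or `"auto"` (default):
#'   the median off-diagonal pairwise distance (median heuristic).
#' @param distance `"euclidean"` (degrees, default) or `"greatcircle"` (km).
#' @return An `n x n` symmetric matrix with unit diagonal and entries in
#'   (0, 1]; the bandwidth used is stored in attribute `"sigma"`.
#' @export
#' @examples
#' w <- spatial_weight_matrix(table1_fixture())
#' range(w)
spatial_weight_matrix <- function(coords, sigma = "auto",
                                  distance = c("euclidean", "greatcircle")) {
  distance <- match.arg(distance)
  cm <- as_coord_matrix(coords)
  n <- nrow(cm)
  if (n < 2) {
    abort("need at least 2 coordinates", class = "agri_size_error")
  }
  dmat <- if (distance == "euclidean") {
    as.matrix(stats::dist(cm))
  } else {
    # geosphere expects (longitude, latitude) pairs
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      j <- seq.int(i + 1, n)
      m[i, j] <- m[j, i] <- geosphere::distGeo(
        cm[i, c(2, 1)], cm[j, c(2, 1), drop = FALSE]
      ) / 1000
    }
    m
  }
  if (identical(sigma, "auto")) {
    off <- dmat[lower.tri(dmat)]
    sigma <- median(off)
    if (sigma <= 0) {
      abort("all coordinates coincide: median pairwise distance is 0, supply sigma explicitly",
            class = "agri_bandwidth_error")
    }
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    abort("sigma must be positive or \"auto\"", class = "agri_value_error")
  }
  w <- exp(-dmat^2 / sigma^2)
  attr(w, "sigma") <- sigma
  w
}

as_coord_matrix <- function(coords) {
  if (is.matrix(coords)) {
    stopifnot(ncol(coords) == 2)
    return(unname(coords))
  }
  if (is.data.frame(coords)) {
    stopifnot(all(c("latitude", "longitude") %in% names(coords)))
    return(cbind(coords$latitude, coords$longitude))
  }
  abort("coords must be a matrix or a data frame with latitude/longitude",
        class = "agri_type_error")
}

#' Fuse spatial and feature-view similarity matrices
#'
#' Convex combination `S = alpha * W_s + (1 - alpha) * W_f` of the spatial
#' weight matrix and a nonspatial feature-similarity matrix. Any symmetric
#' `W_f` with entries in \[0, 1\] is accepted, so alternative feature views
#' are pluggable.
#'
#' @param w_s,w_f Same-shape symmetric similarity matrices.
#' @param alpha_mix Balance in \[0, 1\]: 1 is purely spatial, 0 purely
#'   feature-based.
#' @return The fused similarity matrix.
#' @export
multiview_similarity <- function(w_s, w_f, alpha_mix = 0.5) {
  if (!all(dim(w_s) == dim(w_f))) {
    abort("w_s and w_f must have the same shape", class = "agri_value_error")
  }
  if (alpha_mix < 0 || alpha_mix > 1) {
    abort("alpha_mix must be in [0, 1]", class = "agri_value_error")
  }
  alpha_mix * w_s + (1 - alpha_mix) * w_f
}

#' Spatial multiview outlier detection (SMVOD)
#'
#' Scores each record by how poorly it fits *both* its geographic
#' neighbourhood and the feature cloud simultaneously. Two similarity views
#' are built -- the spatial weight matrix `W_s = exp(-D^2 / sigma^2)` on
#' coordinates and a Gaussian kernel `W_f` on the standardized nonspatial
#' features (bandwidth: median pairwise feature distance) -- and fused as
#' `S = alpha * W_s + (1 - alpha) * W_f`. The per-sample score is
#' `1 - mean of the k largest off-diagonal entries of row i of S`: an
#' ordinary record has peers that are similar under both views at once, so
#' its top fused similarities are high; a spatially inconsistent record
#' (typical values, wrong place) has no row that is close in both views,
#' so even its best peers have depressed fused similarity. The threshold is
#' the `percentile`-th percentile of the scores, exceeded strictly.
#'
#' With `alpha = 1` the score depends only on coordinates; with `alpha = 0`
#' only on features.
#'
#' @param data A record-table tibble (coordinates are taken from its
#'   `latitude`/`longitude` columns unless `coords` is given) or a
#'   `feature_matrix`.
#' @param features Nonspatial feature columns when `data` is a table.
#' @param coords Optional coordinates (see [spatial_weight_matrix()]);
#'   required when `data` is a `feature_matrix`.
#' @param sigma Spatial bandwidth or `"auto"` (median heuristic).
#' @param alpha_mix Spatial/feature balance in \[0, 1\], default 0.5.
#' @param k_peers Number of top peers averaged per row; default
#'   `max(5, ceiling(0.025 * n))`, capped at `n - 1`.
#' @param percentile Threshold percentile in (0, 100), default 95.
#' @param distance Spatial distance type, see [spatial_weight_matrix()].
#' @return An `outlier_result` with scores in \[0, 1\]; the fused similarity
#'   matrix is attached as attribute `"similarity"` of `params`.
#' @export
#' @examples
#' res <- detect_smvod(table1_fixture(), features = c("n", "p", "k", "ph", "ec"))
#' glance(res)
detect_smvod <- function(data, features = NULL, coords = NULL, sigma = "auto",
                         alpha_mix = 0.5, k_peers = NULL, percentile = 95,
                         distance = "euclidean") {
  if (is.null(coords)) {
    if (!is.data.frame(data) ||
        !all(c("latitude", "longitude") %in% names(data))) {
      abort("coords must be supplied unless data has latitude/longitude columns",
            class = "agri_alignment_error")
    }
    coords <- data[, c("latitude", "longitude")]
  }
  fm <- as_feature_matrix(data, features, standardize = TRUE)
  cm <- as_coord_matrix(coords)
  n <- nrow(fm$values)
  if (nrow(cm) != n) {
    abort("coordinate rows do not align with feature rows",
          class = "agri_alignment_error")
  }
  if (n < 3) {
    abort("SMVOD needs at least 3 rows", class = "agri_size_error")
  }

  w_s <- spatial_weight_matrix(cm, sigma = sigma, distance = distance)
  fd <- as.matrix(stats::dist(fm$values))
  fband <- median(fd[lower.tri(fd)])
  if (fband <= 0) fband <- 1 # all rows identical: W_f is all ones either way
  w_f <- exp(-fd^2 / fband^2)
  s <- multiview_similarity(w_s, w_f, alpha_mix)

  if (is.null(k_peers)) {
    k_peers <- max(5, ceiling(0.025 * n))
  }
  k_peers <- min(k_peers, n - 1)
  diag(s) <- -Inf
  top_mean <- apply(s, 1, function(row) {
    mean(sort(row, decreasing = TRUE)[seq_len(k_peers)])
  })
  diag(s) <- 1
  scores <- 1 - top_mean
  threshold <- percentile_threshold(scores, percentile)

  params <- list(sigma = attr(w_s, "sigma"), feature_bandwidth = fband,
                 alpha_mix = alpha_mix, k_peers = k_peers,
                 percentile = percentile, score = "1 - mean top-k fused similarity")
  attr(params, "similarity") <- s
  new_outlier_result(
    scores = scores, threshold = threshold, method = "smvod",
    params = params, row_ids = fm$row_ids
  )
}
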