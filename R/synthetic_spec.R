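#' Default feature means for synthetic agronomic tables
#'
#' Typical magnitudes for the ten agronomic measurements in the emulated
#' study region (soil N/P/K in kg/ha, pH, EC in dS/m, temperature in deg C,
#' rainfall in mm, cultivated area in ha, production in t, yield in kg/ha).
#'
#' @return Named numeric vector of length 10.
#' @export
default_feature_means <- function() {
  c(n = 250, p = 9, k = 82, ph = 7.8, ec = 1.0, temperature = 24.4,
    rainfall = 92, area = 19300, production = 62000, yield = 2170)
}

# marginal standard deviations paired with default_feature_means()
default_feature_sds <- function() {
  c(n = 45, p = 4, k = 21, ph = 0.85, ec = 0.6, temperature = 1.2,
    rainfall = 18, area = 4500, production = 18000, yield = 450)
}

#' Default feature covariance for synthetic agronomic tables
#'
#' Correlated-Gaussian structure: positively correlated soil nutrients
#' (N, P, K), pH tied to EC, temperature anti-correlated with rainfall, a
#' strong area-production-yield production block, and moderate
#' nutrient/rainfall effects on yield so the two natural feature views
#' (soil chemistry vs. production) are not independent.
#'
#' @return A 10 x 10 positive-definite covariance matrix with dimnames.
#' @export
default_feature_cov <- function() {
  nm <- names(default_feature_means())
  d <- length(nm)
  r <- diag(1, d)
  dimnames(r) <- list(nm, nm)
  set_r <- function(a, b, val) {
    r[a, b] <<- val
    r[b, a] <<- val
  }
  set_r("n", "p", 0.30); set_r("n", "k", 0.30); set_r("p", "k", 0.25)
  set_r("ph", "ec", 0.20)
  set_r("temperature", "rainfall", -0.30)
  set_r("area", "production", 0.75)
  set_r("production", "yield", 0.55)
  set_r("area", "yield", 0.10)
  set_r("n", "yield", 0.30); set_r("p", "yield", 0.20); set_r("k", "yield", 0.20)
  set_r("rainfall", "yield", 0.25); set_r("rainfall", "production", 0.20)
  s <- default_feature_sds()
  cov <- r * tcrossprod(s)
  dimnames(cov) <- list(nm, nm)
  cov
}

#' Specify a synthetic labeled agronomic dataset
#'
#' Describes the generating conditions for [generate_dataset()]: correlated
#' Gaussian inlier features, coordinates drawn as Gaussian blobs around
#' well-separated cluster centres inside a regional bounding box, smooth
#' cluster-level feature offsets (so spatial neighbours are more alike than
#' distant records), and injected outliers of three mechanistically distinct
#' kinds at an exact contamination fraction.
#'
#' @param n_inliers Number of clean records.
#' @param contamination Outlier fraction of the *total* table, in \[0, 0.5);
#'   the flagged count is exactly `round(contamination * n_total)`.
#' @param outlier_mix Named proportions over `global`, `spatial`,
#'   `multiview`, summing to 1.
#' @param feature_means,feature_cov Mean vector and positive-semidefinite
#'   covariance of the inlier features.
#' @param global_shift_sigmas Displacement of a global outlier, in marginal
#'   standard deviations (default 6: gross measurement/entry errors).
#' @param spatial_swap_radius Minimum coordinate distance (degrees) between
#'   a spatial outlier and its feature donor.
#' @param bounding_box Numeric `(lat_min, lat_max, long_min, long_max)`;
#'   default the study region's extent, roughly 14.20-14.60 N,
#'   75.65-76.56 E.
#' @param n_spatial_clusters Number of coordinate clusters (default 4).
#' @param cluster_contrast Magnitude of the cluster-level feature offsets in
#'   within-zone standard deviations (default 3: clearly distinct agro-zones,
#'   so a record swapped in from another zone is locally anomalous -- the
#'   regime spatial outliers are defined by -- while remaining globally
#'   typical; set 0 for a spatially homogeneous Gaussian table).
#' @param missing_rate Optional fraction of feature cells masked to `NA`
#'   after generation (default 0).
#' @param seed Integer master seed; every stage derives its own child seed
#'   from it, so the generator is a pure function of this spec.
#'
#' @return A validated `synthetic_spec` object.
#' @export
#' @examples
#' spec <- synthetic_spec(n_inliers = 95, contamination = 0.05, seed = 42)
#' spec$n_outliers
synthetic_spec <- function(n_inliers = 475,
                           contamination = 0.05,
                           outlier_mix = c(global = 1 / 3, spatial = 1 / 3,
                                           multiview = 1 / 3),
                           feature_means = default_feature_means(),
                           feature_cov = default_feature_cov(),
                           global_shift_sigmas = 6,
                           spatial_swap_radius = 0.1,
                           bounding_box = c(lat_min = 14.20, lat_max = 14.60,
                                            long_min = 75.65, long_max = 76.56),
                           n_spatial_clusters = 4,
                           cluster_contrast = 3,
                           missing_rate = 0,
                           seed = 1) {
  if (contamination < 0 || contamination >= 0.5) {
    abort("contamination must be in [0, 0.5)", class = "agri_spec_error")
  }
  mix <- outlier_mix[c("global", "spatial", "multiview")]
  if (anyNA(mix) || any(mix < 0) || abs(sum(mix) - 1) > 1e-12) {
    abort("outlier_mix must be non-negative proportions over global/spatial/multiview summing to 1",
          class = "agri_spec_error")
  }
  d <- length(feature_means)
  if (!is.matrix(feature_cov) || any(dim(feature_cov) != d)) {
    abort("feature_cov must be a d x d matrix matching feature_means",
          class = "agri_spec_error")
  }
  if (max(abs(feature_cov - t(feature_cov))) > 1e-8 * max(abs(feature_cov))) {
    abort("feature_cov must be symmetric", class = "agri_spec_error")
  }
  ev <- eigen(feature_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    abort("feature_cov is not positive-semidefinite", class = "agri_spec_error")
  }
  if (global_shift_sigmas <= 0) {
    abort("global_shift_sigmas must be positive", class = "agri_value_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must be in [0, 1)", class = "agri_spec_error")
  }

  # exact count: n_out with round(contamination * (n_inliers + n_out)) == n_out
  n_out <- round(contamination * n_inliers / (1 - contamination))
  for (cand in unique(pmax(0, n_out + c(0, -1, 1)))) {
    if (round(contamination * (n_inliers + cand)) == cand) {
      n_out <- cand
      break
    }
  }
  if (contamination > 0 && n_out < 1) {
    abort("contamination > 0 but the implied outlier count rounds to zero; increase n_inliers or contamination",
          class = "agri_spec_error")
  }

  if (is.null(names(feature_means))) {
    names(feature_means) <- paste0("f", seq_len(d))
  }
  structure(
    list(n_inliers = n_inliers, contamination = contamination,
         outlier_mix = mix, feature_means = feature_means,
         feature_cov = feature_cov, global_shift_sigmas = global_shift_sigmas,
         spatial_swap_radius = spatial_swap_radius,
         bounding_box = bounding_box,
         n_spatial_clusters = n_spatial_clusters,
         cluster_contrast = cluster_contrast,
         missing_rate = missing_rate, seed = as.integer(seed),
         n_outliers = n_out, n_total = n_inliers + n_out),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_total, " rows (", x$n_outliers, " outliers, ",
      format(x$contamination, digits = 4), " contamination), ",
      length(x$feature_means), " features, ", x$n_spatial_clusters,
      " spatial clusters, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic spec as YAML
#'
#' @param spec A `synthetic_spec`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_synthetic_spec()` returns the
#'   reconstructed, re-validated `synthetic_spec`.
#' @export
write_synthetic_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$outlier_mix <- as.list(spec$outlier_mix)
  obj$feature_means <- as.list(spec$feature_means)
  obj$bounding_box <- as.list(spec$bounding_box)
  obj$feature_cov <- apply(spec$feature_cov, 1, as.numeric, simplify = FALSE)
  obj$n_outliers <- NULL
  obj$n_total <- NULL
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  means <- unlist(obj$feature_means)
  cov <- do.call(rbind, lapply(obj$feature_cov, unlist))
  dimnames(cov) <- list(names(means), names(means))
  synthetic_spec(
    n_inliers = obj$n_inliers, contamination = obj$contamination,
    outlier_mix = unlist(obj$outlier_mix), feature_means = means,
    feature_cov = cov, global_shift_sigmas = obj$global_shift_sigmas,
    spatial_swap_radius = obj$spatial_swap_radius,
    bounding_box = unlist(obj$bounding_box),
    n_spatial_clusters = obj$n_spatial_clusters,
    cluster_contrast = obj$cluster_contrast %||% 1,
    missing_rate = obj$missing_rate %||% 0,
    seed = obj$seed
  )
}
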