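two_cluster_spec <- function(contrast = 8, n = 120, contamination = 0.1,
                             seed = 1, mix = c(global = 0, spatial = 1,
                                              multiview = 0)) {
  synthetic_spec(
    n_inliers = n, contamination = contamination, outlier_mix = mix,
    feature_means = c(f1 = 0, f2 = 0),
    feature_cov = diag(2),
    n_spatial_clusters = 2, cluster_contrast = contrast, seed = seed
  )
}

test_that("contamination counts are exact and labels align with types", {
  ds <- generate_dataset(synthetic_spec(n_inliers = 95, contamination = 0.05,
                                        seed = 42))
  expect_equal(nrow(ds$table), 100)
  expect_equal(sum(ds$labels$is_outlier), 5)
  expect_identical(ds$labels$outlier_type == "none", !ds$labels$is_outlier)

  # full pipeline bookkeeping on the default mixed contamination
  ds2 <- generate_dataset(synthetic_spec(n_inliers = 190, contamination = 0.05,
                                         seed = 3))
  expect_equal(sum(ds2$labels$is_outlier),
               round(0.05 * nrow(ds2$table)))
  expect_setequal(unique(ds2$labels$outlier_type),
                  c("none", "global", "spatial", "multiview"))
})

test_that("generation is a pure function of the spec", {
  spec <- synthetic_spec(n_inliers = 95, contamination = 0.05, seed = 42)
  ds1 <- generate_dataset(spec)
  ds2 <- generate_dataset(spec)
  expect_identical(ds1$table, ds2$table)
  expect_identical(ds1$labels, ds2$labels)
  ds3 <- generate_dataset(synthetic_spec(n_inliers = 95, contamination = 0.05,
                                         seed = 43))
  expect_false(identical(ds1$table, ds3$table))
})

test_that("clean tables match the requested distribution", {
  spec <- synthetic_spec(n_inliers = 2000, contamination = 0,
                         cluster_contrast = 0, seed = 11)
  ds <- generate_dataset(spec)
  expect_true(all(ds$labels$outlier_type == "none"))
  mu <- spec$feature_means
  sds <- sqrt(diag(spec$feature_cov))
  emp <- colMeans(ds$table[, names(mu)])
  expect_true(all(abs(emp - mu) < 4 * sds / sqrt(nrow(ds$table))))
  bb <- spec$bounding_box
  expect_true(all(ds$table$latitude >= bb[1] & ds$table$latitude <= bb[2]))
  expect_true(all(ds$table$longitude >= bb[3] & ds$table$longitude <= bb[4]))
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(contamination = 0.6), class = "agri_spec_error")
  expect_error(synthetic_spec(outlier_mix = c(global = 0.6, spatial = 0.6,
                                              multiview = 0)),
               class = "agri_spec_error")
  bad_cov <- matrix(c(1, 2, 2, 1), 2) # indefinite
  expect_error(synthetic_spec(feature_means = c(a = 0, b = 0),
                              feature_cov = bad_cov),
               class = "agri_spec_error")
  expect_error(synthetic_spec(n_inliers = 95, contamination = 0.002),
               class = "agri_spec_error")
})

test_that("global injection displaces rows by the requested magnitude", {
  set.seed(9)
  x <- matrix(rnorm(200 * 4), 200, 4)
  fm <- as_feature_matrix(toy_table(x), standardize = TRUE)
  out <- inject_global_outliers(fm, rows = 7, shift_sigmas = 6, seed = 2)
  delta <- out$values[7, ] - fm$values[7, ]
  moved <- which(abs(delta) > 0)
  expect_gte(length(moved), 2) # at least ceiling(d/2) coordinates shifted
  sig <- apply(fm$values, 2, function(c) sqrt(mean((c - mean(c))^2)))
  expect_equal(abs(delta[moved]), 6 * sig[moved], tolerance = 1e-12)
  expect_equal(out$values[-7, ], fm$values[-7, ])

  expect_identical(inject_global_outliers(fm, integer(0), 6)$values, fm$values)
  expect_error(inject_global_outliers(fm, 1, shift_sigmas = 0),
               class = "agri_value_error")
})

test_that("spatial injection yields globally typical, locally anomalous rows", {
  ds <- generate_dataset(two_cluster_spec(contrast = 8, seed = 4))
  rows <- which(ds$labels$outlier_type == "spatial")
  expect_gt(length(rows), 0)
  x <- as.matrix(ds$table[, c("f1", "f2")])
  inl <- !ds$labels$is_outlier
  # globally typical: inside the inlier range
  expect_true(all(x[rows, 1] >= min(x[inl, 1]) & x[rows, 1] <= max(x[inl, 1])))
  # locally anomalous: > 3 local sds from the 5 nearest spatial neighbours
  coords <- as.matrix(ds$table[, c("latitude", "longitude")])
  for (i in rows) {
    d <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
    d[i] <- Inf
    nb <- intersect(order(d), which(inl))[1:5]
    local_mu <- colMeans(x[nb, , drop = FALSE])
    local_sd <- apply(x[nb, , drop = FALSE], 2, sd)
    expect_gt(max(abs(x[i, ] - local_mu) / pmax(local_sd, 1e-12)), 3)
  }
  # disjoint per-cluster feature ranges: injected values come from the
  # opposite cluster's range
  cl <- ds$cluster
  for (j in 1:2) {
    r1 <- range(x[inl & cl == 1, j])
    r2 <- range(x[inl & cl == 2, j])
    if (r1[2] < r2[1] || r2[2] < r1[1]) {
      for (i in rows) {
        own <- if (cl[i] == 1) r1 else r2
        other <- if (cl[i] == 1) r2 else r1
        expect_true(x[i, j] >= other[1] && x[i, j] <= other[2])
      }
    }
  }
})

test_that("spatial injection requires at least two clusters", {
  spec <- synthetic_spec(n_inliers = 40, contamination = 0,
                         n_spatial_clusters = 1, seed = 1)
  ds <- generate_dataset(spec)
  expect_error(inject_spatial_outliers(ds, rows = 3),
               class = "agri_unsupported_error")
  expect_identical(inject_spatial_outliers(generate_dataset(two_cluster_spec()),
                                           integer(0))$table,
                   generate_dataset(two_cluster_spec())$table)
})

test_that("multiview injection splices marginally typical halves", {
  spec <- synthetic_spec(n_inliers = 150, contamination = 0,
                         cluster_contrast = 0, seed = 6)
  ds <- generate_dataset(spec)
  feats <- names(spec$feature_means)
  x0 <- as.matrix(ds$table[, feats])
  rows <- c(4, 19, 77)
  ds2 <- inject_multiview_outliers(ds, rows, seed = 8)
  x1 <- as.matrix(ds2$table[, feats])
  v1 <- seq_len(ceiling(length(feats) / 2))
  v2 <- setdiff(seq_along(feats), v1)
  for (i in rows) {
    # each half matches some other row's half exactly
    m1 <- which(apply(x0[, v1, drop = FALSE], 1,
                      function(r) all(r == x1[i, v1])))
    m2 <- which(apply(x0[, v2, drop = FALSE], 1,
                      function(r) all(r == x1[i, v2])))
    expect_true(length(setdiff(m1, i)) >= 1)
    expect_true(length(setdiff(m2, i)) >= 1)
  }
  expect_equal(x1[-rows, ], x0[-rows, ])
  expect_true(all(ds2$labels$outlier_type[rows] == "multiview"))

  few <- synthetic_spec(n_inliers = 30, contamination = 0,
                        feature_means = c(a = 0, b = 0, c = 0),
                        feature_cov = diag(3), seed = 1)
  expect_error(inject_multiview_outliers(generate_dataset(few), 2),
               class = "agri_unsupported_error")
})

test_that("multiview outliers break strong cross-view correlation", {
  # two views, within-pair correlation 0.99 across views
  r <- diag(4)
  r[1, 3] <- r[3, 1] <- 0.99
  r[2, 4] <- r[4, 2] <- 0.99
  spec <- synthetic_spec(
    n_inliers = 190, contamination = 0.05,
    outlier_mix = c(global = 0, spatial = 0, multiview = 1),
    feature_means = c(a = 0, b = 0, c = 0, d = 0), feature_cov = r,
    cluster_contrast = 0, seed = 2
  )
  ds <- generate_dataset(spec)
  x <- as.matrix(ds$table[, c("a", "b", "c", "d")])
  inl <- !ds$labels$is_outlier
  # least-squares oracle: regress view 2 on view 1, fitted on inliers
  fit <- lm.fit(cbind(1, x[inl, 1:2]), x[inl, 3:4])
  pred <- cbind(1, x[, 1:2]) %*% fit$coefficients
  resid_score <- sqrt(rowSums((x[, 3:4] - pred)^2))
  cutoff <- quantile(resid_score, 0.9)
  # spliced rows rank in the top decile of cross-view residuals (a donor
  # pair can be mutually consistent by chance, hence the 90% bar)
  expect_gte(mean(resid_score[ds$labels$is_outlier] > cutoff), 0.9)
})

test_that("label bookkeeping survives an injection sequence", {
  ds <- generate_dataset(synthetic_spec(n_inliers = 100, contamination = 0,
                                        seed = 13))
  feats <- names(ds$spec$feature_means)
  x0 <- as.matrix(ds$table[, feats])
  ds <- inject_spatial_outliers(ds, rows = c(2, 50), seed = 1)
  ds <- inject_multiview_outliers(ds, rows = c(7, 80), seed = 2)
  x1 <- as.matrix(ds$table[, feats])
  modified <- which(rowSums(x1 != x0) > 0)
  expect_setequal(modified, c(2, 50, 7, 80))
  expect_setequal(which(ds$labels$is_outlier), modified)
  expect_equal(ds$labels$outlier_type[c(2, 50)], c("spatial", "spatial"))
  expect_equal(ds$labels$outlier_type[c(7, 80)], c("multiview", "multiview"))
})

test_that("homogeneous clean features pass a marginal normality screen", {
  # Gaussian core isolated (no spatial mean structure): Shapiro-Wilk at the
  # 0.1% level should pass for every feature in >= 95% of replicates
  pass <- vapply(1:100, function(r) {
    ds <- generate_dataset(synthetic_spec(n_inliers = 2000, contamination = 0,
                                          cluster_contrast = 0, seed = r))
    p <- vapply(names(ds$spec$feature_means),
                function(f) shapiro.test(ds$table[[f]])$p.value, numeric(1))
    all(p > 0.001)
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("spec YAML and dataset CSV round trips are lossless", {
  spec <- synthetic_spec(n_inliers = 60, contamination = 0.05, seed = 21)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_spec(spec, tmp)
  spec2 <- read_synthetic_spec(tmp)
  # YAML carries 15 significant digits, so regenerated values agree to that
  expect_equal(generate_dataset(spec)$table, generate_dataset(spec2)$table,
               tolerance = 1e-10)

  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  write_labeled_dataset(ds, dir)
  back <- read_labeled_dataset(file.path(dir, "table.csv"),
                               file.path(dir, "labels.csv"))
  expect_equal(back$labels$is_outlier, ds$labels$is_outlier)
  expect_equal(back$table$ph, ds$table$ph)
})
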