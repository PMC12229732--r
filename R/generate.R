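#' Generate a labeled synthetic agronomic dataset
#'
#' Draws inlier records from the spec's correlated Gaussian, places them in
#' Gaussian coordinate blobs around well-separated cluster centres inside
#' the bounding box, adds cluster-level feature offsets (spatial smoothness),
#' samples categorical crop/season/soil labels, injects the three outlier
#' kinds per `outlier_mix`, shuffles the rows and returns the table together
#' with aligned ground-truth labels. The result is a pure function of the
#' spec: identical specs (including seed) give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A `labeled_dataset`: list with `table` (record tibble including
#'   `latitude`/`longitude` and categorical columns), `labels` (tibble
#'   `row_id`, `is_outlier`, `outlier_type`), `cluster` (integer vector of
#'   coordinate-cluster assignments) and the `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_inliers = 95, contamination = 0.05,
#'                                       seed = 42))
#' table(ds$labels$outlier_type)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- child_seeds(spec$seed, 9)
  n <- spec$n_total
  d <- length(spec$feature_means)
  feats <- names(spec$feature_means)

  # -- spatial clusters: greedy farthest-point centres from a candidate pool
  bb <- spec$bounding_box
  k <- spec$n_spatial_clusters
  centers <- with_rng(seeds[1], {
    pad_lat <- 0.1 * (bb[2] - bb[1])
    pad_long <- 0.1 * (bb[4] - bb[3])
    cand <- cbind(runif(max(100, 10 * k), bb[1] + pad_lat, bb[2] - pad_lat),
                  runif(max(100, 10 * k), bb[3] + pad_long, bb[4] - pad_long))
    sel <- sample.int(nrow(cand), 1)
    while (length(sel) < k) {
      dmin <- apply(cand, 1, function(p) {
        min(sqrt((p[1] - cand[sel, 1])^2 + (p[2] - cand[sel, 2])^2))
      })
      sel <- c(sel, which.max(dmin))
    }
    cand[sel, , drop = FALSE]
  })
  cluster <- with_rng(seeds[2], sample.int(k, n, replace = TRUE))
  coords <- with_rng(seeds[3], {
    sd_lat <- (bb[2] - bb[1]) / 12
    sd_long <- (bb[4] - bb[3]) / 12
    cbind(
      latitude = pmin(pmax(centers[cluster, 1] + rnorm(n, 0, sd_lat), bb[1]), bb[2]),
      longitude = pmin(pmax(centers[cluster, 2] + rnorm(n, 0, sd_long), bb[3]), bb[4])
    )
  })

  # -- features: MVN inliers plus smooth cluster-level mean offsets
  sds <- sqrt(pmax(diag(spec$feature_cov), 0))
  x <- with_rng(seeds[4], {
    z <- matrix(rnorm(n * d), n, d)
    offsets <- matrix(rnorm(k * d, 0, 1), k, d) * spec$cluster_contrast
    offsets <- sweep(offsets, 2, sds, "*")
    base <- z %*% sqrt_psd(spec$feature_cov)
    sweep(base + offsets[cluster, , drop = FALSE], 2, spec$feature_means, "+")
  })
  colnames(x) <- feats

  vocab <- agri_vocabularies()
  cats <- with_rng(seeds[5], {
    soil_levels <- vocab$soil[((seq_len(k) - 1) %% length(vocab$soil)) + 1]
    dominant <- soil_levels[cluster]
    soil <- ifelse(runif(n) < 0.7, dominant,
                   sample(vocab$soil[1:5], n, replace = TRUE))
    list(
      crop = sample(vocab$crop[1:5], n, replace = TRUE),
      season = sample(vocab$season, n, replace = TRUE),
      soil = soil
    )
  })

  # -- ground truth and injections
  is_outlier <- rep(FALSE, n)
  outlier_type <- rep("none", n)
  if (spec$n_outliers > 0) {
    rows <- with_rng(seeds[6], sample.int(n, spec$n_outliers))
    counts <- allocate_counts(spec$n_outliers, spec$outlier_mix)
    type_of <- rep(names(counts), counts)
    is_outlier[rows] <- TRUE
    outlier_type[rows] <- type_of

    inliers <- which(!is_outlier)
    g_rows <- rows[type_of == "global"]
    s_rows <- rows[type_of == "spatial"]
    m_rows <- rows[type_of == "multiview"]
    if (length(g_rows) > 0) {
      x <- shift_rows(x, g_rows, spec$global_shift_sigmas,
                      sigmas = apply(x, 2, pop_sd), seed = seeds[7])
    }
    if (length(s_rows) > 0) {
      x <- swap_rows_across_clusters(x, s_rows, cluster, coords,
                                     donors = inliers,
                                     radius = spec$spatial_swap_radius,
                                     seed = seeds[8])
    }
    if (length(m_rows) > 0) {
      x <- splice_views(x, m_rows, donors = inliers, seed = seeds[9])
    }
  }

  if (spec$missing_rate > 0) {
    x <- with_rng(spec$seed + 1L, {
      mask <- matrix(runif(n * d) < spec$missing_rate, n, d)
      x[mask] <- NA_real_
      x
    })
  }

  # -- shuffle and assemble
  perm <- with_rng(seeds[2] + 1L, sample.int(n))
  tab <- tibble::tibble(
    row_id = seq_len(n),
    !!!as.data.frame(x[perm, , drop = FALSE]),
    latitude = coords[perm, "latitude"],
    longitude = coords[perm, "longitude"],
    crop = cats$crop[perm], season = cats$season[perm], soil = cats$soil[perm]
  )
  labels <- tibble::tibble(
    row_id = seq_len(n),
    is_outlier = is_outlier[perm],
    outlier_type = outlier_type[perm]
  )
  structure(
    list(table = tab, labels = labels, cluster = cluster[perm], spec = spec),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$table), " rows, ",
      sum(x$labels$is_outlier), " labeled outliers (",
      paste(names(table(x$labels$outlier_type[x$labels$is_outlier])),
            table(x$labels$outlier_type[x$labels$is_outlier]),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# displace rows by shift_sigmas marginal sds over a random >= d/2 feature subset
shift_rows <- function(x, rows, shift_sigmas, sigmas, seed) {
  d <- ncol(x)
  with_rng(seed, {
    for (i in rows) {
      m <- sample(seq.int(ceiling(d / 2), d), 1)
      feats <- sample.int(d, m)
      signs <- sample(c(-1, 1), m, replace = TRUE)
      x[i, feats] <- x[i, feats] + signs * shift_sigmas * sigmas[feats]
    }
    x
  })
}

# give each selected row the feature vector of a donor in another cluster
swap_rows_across_clusters <- function(x, rows, cluster, coords, donors,
                                      radius, seed) {
  with_rng(seed, {
    for (i in rows) {
      pool <- donors[cluster[donors] != cluster[i]]
      if (length(pool) == 0) {
        abort("spatial outlier injection needs at least 2 spatial clusters",
              class = "agri_unsupported_error")
      }
      dist_i <- sqrt((coords[pool, 1] - coords[i, 1])^2 +
                       (coords[pool, 2] - coords[i, 2])^2)
      far <- pool[dist_i > radius]
      if (length(far) == 0) far <- pool[which.max(dist_i)]
      donor <- far[sample.int(length(far), 1)]
      x[i, ] <- x[donor, ]
    }
    x
  })
}

# replace each half of the feature vector with the half of a different donor
splice_views <- function(x, rows, donors, seed) {
  d <- ncol(x)
  if (d < 4) {
    abort("multiview outlier injection needs at least 4 features",
          class = "agri_unsupported_error")
  }
  v1 <- seq_len(ceiling(d / 2))
  v2 <- setdiff(seq_len(d), v1)
  with_rng(seed, {
    for (i in rows) {
      ab <- sample(setdiff(donors, i), 2)
      x[i, v1] <- x[ab[1], v1]
      x[i, v2] <- x[ab[2], v2]
    }
    x
  })
}

#' Inject gross global outliers into a feature matrix
#'
#' Each selected row is displaced by `shift_sigmas` marginal standard
#' deviations along a random sign pattern over a random subset of at least
#' half the features; other rows are untouched. On a standardized matrix the
#' displacement is in z-score units; on a raw matrix the empirical
#' (population) column standard deviations are used.
#'
#' @param matrix A `feature_matrix` (see [extract_features()]).
#' @param rows Integer row indices to corrupt.
#' @param shift_sigmas Positive displacement magnitude in marginal sds.
#' @param seed Integer seed.
#' @return The modified `feature_matrix`.
#' @export
inject_global_outliers <- function(matrix, rows, shift_sigmas, seed = 1) {
  fm <- as_feature_matrix(matrix)
  if (shift_sigmas <= 0) {
    abort("shift_sigmas must be positive", class = "agri_value_error")
  }
  if (length(rows) == 0) {
    return(fm)
  }
  stopifnot(all(rows >= 1), all(rows <= nrow(fm$values)))
  sig <- apply(fm$values, 2, pop_sd)
  sig[sig == 0] <- 1
  fm$values <- shift_rows(fm$values, rows, shift_sigmas, sigmas = sig,
                          seed = seed)
  fm
}

#' Inject spatial outliers into a labeled dataset
#'
#' Each selected row keeps its coordinates but receives the full feature
#' vector of a randomly chosen inlier from a *different* spatial cluster at
#' coordinate distance greater than `swap_radius` -- globally typical values
#' that are anomalous for their neighbourhood.
#'
#' @param dataset A `labeled_dataset` from [generate_dataset()].
#' @param rows Row indices (positions in `dataset$table`) to corrupt.
#' @param swap_radius Minimum donor distance in coordinate degrees; defaults
#'   to the spec's `spatial_swap_radius`.
#' @param seed Integer seed.
#' @return The modified `labeled_dataset` with labels updated.
#' @export
inject_spatial_outliers <- function(dataset, rows,
                                    swap_radius = dataset$spec$spatial_swap_radius,
                                    seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (length(unique(dataset$cluster)) < 2) {
    abort("spatial outlier injection needs at least 2 spatial clusters",
          class = "agri_unsupported_error")
  }
  if (length(rows) == 0) {
    return(dataset)
  }
  feats <- names(dataset$spec$feature_means)
  x <- as.matrix(dataset$table[, feats, drop = FALSE])
  coords <- cbind(dataset$table$latitude, dataset$table$longitude)
  donors <- which(!dataset$labels$is_outlier)
  donors <- setdiff(donors, rows)
  x <- swap_rows_across_clusters(x, rows, dataset$cluster, coords,
                                 donors = donors, radius = swap_radius,
                                 seed = seed)
  dataset$table[, feats] <- as.data.frame(x)
  dataset$labels$is_outlier[rows] <- TRUE
  dataset$labels$outlier_type[rows] <- "spatial"
  dataset
}

#' Inject multiview-inconsistent outliers into a labeled dataset
#'
#' The feature set is split into two halves (views). For each selected row,
#' each half is replaced by the corresponding half of a different randomly
#' chosen inlier: each view is marginally typical, but the combination is
#' inconsistent with the joint distribution.
#'
#' @inheritParams inject_spatial_outliers
#' @return The modified `labeled_dataset` with labels updated.
#' @export
inject_multiview_outliers <- function(dataset, rows, seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  feats <- names(dataset$spec$feature_means)
  if (length(feats) < 4) {
    abort("multiview outlier injection needs at least 4 features",
          class = "agri_unsupported_error")
  }
  if (length(rows) == 0) {
    return(dataset)
  }
  x <- as.matrix(dataset$table[, feats, drop = FALSE])
  donors <- setdiff(which(!dataset$labels$is_outlier), rows)
  x <- splice_views(x, rows, donors = donors, seed = seed)
  dataset$table[, feats] <- as.data.frame(x)
  dataset$labels$is_outlier[rows] <- TRUE
  dataset$labels$outlier_type[rows] <- "multiview"
  dataset
}

#' Write / read a labeled dataset as CSV
#'
#' Writes `table.csv` (the record table) and `labels.csv` (`row_id`,
#' `is_outlier`, `outlier_type`) into a directory.
#'
#' @param dataset A `labeled_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly; `read_labeled_dataset()` returns a
#'   `labeled_dataset` (without cluster assignments, which are not part of
#'   the on-disk contract).
#' @export
write_labeled_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$table, file.path(dir, "table.csv"), progress = FALSE)
  readr::write_csv(dataset$labels, file.path(dir, "labels.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_labeled_dataset
#' @param table_path,labels_path CSV paths as written by
#'   `write_labeled_dataset()`.
#' @export
read_labeled_dataset <- function(table_path, labels_path) {
  tab <- readr::read_csv(table_path, show_col_types = FALSE, progress = FALSE)
  labels <- readr::read_csv(labels_path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("row_id", "is_outlier", "outlier_type") %in% names(labels)),
            nrow(tab) == nrow(labels))
  if (!"row_id" %in% names(tab)) {
    tab <- tibble::add_column(tab, row_id = seq_len(nrow(tab)), .before = 1)
  }
  structure(list(table = tab, labels = labels, cluster = NULL, spec = NULL),
            class = "labeled_dataset")
}
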