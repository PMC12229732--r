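#' Isolation forest
#'
#' Ensemble of random binary isolation trees: each tree is grown on a
#' seeded random subsample of `subsample` rows by repeatedly picking a
#' uniformly random feature and a uniformly random split value between that
#' feature's min and max in the node, until points are isolated or the
#' height cap `ceiling(log2(subsample))` is reached. Anomalies are isolated
#' in few splits, so short average path lengths mean outliers.
#'
#' A point's path length in a tree is the number of edges to its leaf plus
#' the adjustment `c(leaf_size)`, where
#' `c(m) = 2 * H(m - 1) - 2 * (m - 1) / m` (harmonic-number form) is the
#' expected unsuccessful-search path length in a binary search tree of `m`
#' points. The anomaly score is `2^(-E[h(x)] / c(subsample))`, in (0, 1)
#' with higher meaning more anomalous; the threshold is the
#' `(1 - contamination)` quantile of the scores, exceeded strictly.
#'
#' @param data A record-table tibble or `feature_matrix`.
#' @param features Feature columns when `data` is a table.
#' @param n_trees Number of trees (default 100).
#' @param subsample Subsample size per tree (default 256, capped at `n`).
#' @param contamination Assumed outlier fraction in (0, 0.5], default 0.1.
#' @param seed Integer seed for subsampling and splits.
#' @return An `outlier_result` with scores in (0, 1).
#' @export
#' @examples
#' fm <- extract_features(table1_fixture(), c("n", "p", "k", "ph", "ec"))
#' glance(detect_isolation_forest(fm, seed = 1))
detect_isolation_forest <- function(data, features = NULL, n_trees = 100,
                                    subsample = 256, contamination = 0.1,
                                    seed = 1) {
  if (contamination <= 0 || contamination > 0.5) {
    abort("contamination must be in (0, 0.5]", class = "agri_value_error")
  }
  fm <- as_feature_matrix(data, features, standardize = FALSE)
  x <- fm$values
  n <- nrow(x)
  if (n < 2 || subsample < 2) {
    abort("isolation forest needs n >= 2 and subsample >= 2",
          class = "agri_size_error")
  }
  psi <- min(subsample, n)
  height_limit <- ceiling(log2(psi))

  tree_seeds <- child_seeds(seed, n_trees)
  path_sum <- rep(0, n)
  for (t in seq_len(n_trees)) {
    h_tree <- with_rng(tree_seeds[t], {
      idx <- sample.int(n, psi)
      tree <- grow_itree(x[idx, , drop = FALSE], height_limit)
      itree_path_length(tree, x)
    })
    path_sum <- path_sum + h_tree
  }
  e_h <- path_sum / n_trees
  scores <- 2^(-e_h / harmonic_path_norm(psi))
  threshold <- unname(quantile(scores, 1 - contamination, type = 7))

  new_outlier_result(
    scores = scores, threshold = threshold, method = "isolation_forest",
    params = list(n_trees = n_trees, subsample = psi,
                  contamination = contamination, seed = seed,
                  height_limit = height_limit),
    row_ids = fm$row_ids
  )
}

# expected path length c(m) of unsuccessful BST search over m points
harmonic_path_norm <- function(m) {
  if (m <= 1) {
    return(0)
  }
  if (m == 2) {
    return(1)
  }
  h <- log(m - 1) + 0.5772156649015329 # harmonic number H(m-1)
  2 * h - 2 * (m - 1) / m
}

# grow one isolation tree on the subsample (recursive node list)
grow_itree <- function(x, height_limit, depth = 0) {
  n <- nrow(x)
  if (n <= 1 || depth >= height_limit) {
    return(list(leaf = TRUE, size = n))
  }
  rng <- apply(x, 2, range)
  splittable <- which(rng[1, ] < rng[2, ])
  if (length(splittable) == 0) { # all duplicate rows
    return(list(leaf = TRUE, size = n))
  }
  f <- splittable[sample.int(length(splittable), 1)]
  sv <- runif(1, rng[1, f], rng[2, f])
  left <- x[, f] < sv
  list(leaf = FALSE, feature = f, split = sv,
       left = grow_itree(x[left, , drop = FALSE], height_limit, depth + 1),
       right = grow_itree(x[!left, , drop = FALSE], height_limit, depth + 1))
}

# path length h(x) for every row of x down one tree (vectorized routing)
itree_path_length <- function(tree, x) {
  h <- numeric(nrow(x))
  route <- function(node, idx, depth) {
    if (length(idx) == 0) {
      return(invisible())
    }
    if (node$leaf) {
      h[idx] <<- depth + harmonic_path_norm(node$size)
      return(invisible())
    }
    left <- x[idx, node$feature] < node$split
    route(node$left, idx[left], depth + 1)
    route(node$right, idx[!left], depth + 1)
  }
  route(tree, seq_len(nrow(x)), 0)
  h
}
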