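# Independent brute-force oracles used to cross-check the detectors.
# Deliberately simple and slow: they share no code with the implementation.

# type-7 (linear interpolation) quantile computed from first principles
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - (lo - 1)) * (xs[hi] - xs[lo])
}

# iterative univariate/multivariate IQR filtering by direct looping
oracle_iterative_iqr <- function(x, k, max_iterations = 100) {
  x <- as.matrix(x)
  removed_at <- rep(0L, nrow(x))
  alive <- rep(TRUE, nrow(x))
  for (it in seq_len(max_iterations)) {
    idx <- which(alive)
    if (length(idx) < 4) break
    bad <- logical(length(idx))
    for (j in seq_len(ncol(x))) {
      col <- x[idx, j]
      q1 <- oracle_quantile(col, 0.25)
      q3 <- oracle_quantile(col, 0.75)
      fence <- k * (q3 - q1)
      bad <- bad | col < (q1 - fence) | col > (q3 + fence)
    }
    if (!any(bad)) break
    removed_at[idx[bad]] <- it
    alive[idx[bad]] <- FALSE
  }
  removed_at
}

# squared Mahalanobis distances via an explicit matrix inverse, row by row
oracle_mahalanobis <- function(x, mu, sigma) {
  inv <- solve(sigma)
  apply(x, 1, function(r) {
    d <- r - mu
    as.numeric(t(d) %*% inv %*% d)
  })
}

# truncated-SVD residual row norms via eigen-analysis of the Gram matrix
oracle_svd_residual <- function(x, r) {
  xc <- sweep(x, 2, colMeans(x), "-")
  eg <- eigen(crossprod(xc), symmetric = TRUE)
  v <- eg$vectors[, seq_len(r), drop = FALSE]
  resid <- xc - xc %*% v %*% t(v)
  sqrt(rowSums(resid^2))
}

# exact one-class SVM dual by KKT active-set enumeration:
#   minimize 0.5 * a' K a  s.t.  sum(a) = 1, 0 <= a_i <= cap
# For each assignment of variables to {lower, upper, free}, solve the
# equality-constrained system and check primal feasibility + KKT signs.
oracle_ocsvm_dual <- function(K, cap) {
  n <- nrow(K)
  best <- NULL
  states <- expand.grid(rep(list(0:2), n)) # 0 = at 0, 1 = at cap, 2 = free
  for (s in seq_len(nrow(states))) {
    st <- as.integer(states[s, ])
    free <- which(st == 2)
    upper <- which(st == 1)
    if (length(free) == 0 && abs(length(upper) * cap - 1) > 1e-12) next
    a <- numeric(n)
    a[upper] <- cap
    if (length(free) > 0) {
      kff <- K[free, free, drop = FALSE]
      rhs <- -K[free, upper, drop = FALSE] %*% rep(cap, length(upper))
      m <- rbind(cbind(kff, 1), c(rep(1, length(free)), 0))
      sol <- tryCatch(solve(m, c(rhs, 1 - length(upper) * cap)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      a[free] <- sol[seq_along(free)]
      lambda <- sol[length(sol)]
    } else {
      lambda <- NULL
    }
    if (any(a < -1e-9) || any(a > cap + 1e-9)) next
    grad <- as.numeric(K %*% a)
    if (is.null(lambda)) {
      lambda <- -max(grad[upper])
    }
    kkt <- all(grad[st == 0] + lambda >= -1e-7) &&
      all(grad[st == 1] + lambda <= 1e-7) &&
      (length(free) == 0 || all(abs(grad[free] + lambda) < 1e-7))
    if (!kkt) next
    obj <- 0.5 * sum(a * grad)
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(a = a, obj = obj)
    }
  }
  best$a
}

# tiny record-table builder for unit tests
toy_table <- function(x, names = paste0("f", seq_len(ncol(x)))) {
  x <- as.matrix(x)
  colnames(x) <- names
  tibble::as_tibble(as.data.frame(x))
}
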