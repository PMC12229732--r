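#' Iterative interquartile-range outlier removal
#'
#' Per iteration, for every feature the first and third quartiles (Q1, Q3,
#' linear-interpolation/type-7 convention) and IQR = Q3 - Q1 are computed on
#' the rows that currently survive. A row is removed in that iteration if
#' *any* of its feature values falls below `Q1 - k * IQR` or above
#' `Q3 + k * IQR` (union rule: the procedure removes whole records). Fences
#' are then recomputed on the survivors, and the loop stops when an
#' iteration removes nothing or `max_iterations` is reached. Re-estimating
#' the quartiles after each removal counters masking: a gross outlier can
#' inflate the IQR enough to hide milder ones until it is gone.
#'
#' Scores are the iteration at which a row was removed (0 for survivors),
#' with threshold 0, so `score > threshold` marks exactly the removed rows.
#'
#' @param data A record-table tibble or `feature_matrix`. Quartiles are
#'   taken on the raw feature values; standardization does not change which
#'   rows are fenced.
#' @param features Feature columns (default the agronomic set) when `data`
#'   is a table.
#' @param k Positive fence multiplier; 1.5 is the common default, 3.0 a
#'   conservative alternative.
#' @param max_iterations Iteration cap (default 100).
#' @return An `outlier_result`; `params` records `k`, the quartile type and
#'   the number of iterations run.
#' @export
#' @examples
#' res <- detect_iterative_iqr(table1_fixture(), features = c("ph", "ec"))
#' glance(res)
detect_iterative_iqr <- function(data, features = NULL, k = 1.5,
                                 max_iterations = 100) {
  if (k <= 0) {
    abort("k must be positive", class = "agri_value_error")
  }
  fm <- as_feature_matrix(data, features, standardize = FALSE)
  x <- fm$values
  n <- nrow(x)
  if (n < 4) {
    abort("iterative IQR needs at least 4 rows for quartiles",
          class = "agri_size_error")
  }

  removed_at <- rep(0L, n)
  alive <- rep(TRUE, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iterations) {
      iter <- iter - 1L
      break
    }
    idx <- which(alive)
    if (length(idx) < 4) {
      iter <- iter - 1L
      break
    }
    q1 <- apply(x[idx, , drop = FALSE], 2, quantile, probs = 0.25, type = 7)
    q3 <- apply(x[idx, , drop = FALSE], 2, quantile, probs = 0.75, type = 7)
    iqr <- q3 - q1
    lo <- q1 - k * iqr
    hi <- q3 + k * iqr
    viol <- idx[apply(
      sweep(x[idx, , drop = FALSE], 2, lo, "<") |
        sweep(x[idx, , drop = FALSE], 2, hi, ">"),
      1, any
    )]
    if (length(viol) == 0) {
      break
    }
    removed_at[viol] <- iter
    alive[viol] <- FALSE
  }

  new_outlier_result(
    scores = as.numeric(removed_at), threshold = 0,
    method = "iterative_iqr",
    params = list(k = k, quartile_type = 7, max_iterations = max_iterations,
                  iterations = iter),
    row_ids = fm$row_ids
  )
}
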