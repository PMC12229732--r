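test_that("confusion counts are exact", {
  cm <- confusion_from_labels(rep(FALSE, 7), rep(FALSE, 7))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 0L, fp = 0L, fn = 0L, tn = 7L),
               ignore_attr = TRUE)

  cm2 <- confusion_from_labels(c(TRUE, TRUE, FALSE, FALSE),
                               c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(1, 1, 1, 1))

  set.seed(77)
  for (case in 1:1000) {
    n <- sample(1:30, 1)
    truth <- runif(n) < 0.3
    pred <- runif(n) < 0.3
    cm <- confusion_from_labels(truth, pred)
    # brute-force counting oracle
    counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
    for (i in seq_len(n)) {
      key <- if (truth[i] && pred[i]) "tp" else if (!truth[i] && pred[i]) "fp"
      else if (truth[i]) "fn" else "tn"
      counts[key] <- counts[key] + 1
    }
    expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), unname(counts))
    expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, n)
  }
  expect_error(confusion_from_labels(c(TRUE, FALSE), TRUE),
               class = "agri_alignment_error")
})

test_that("metric formulas, degenerate flags and exact accuracy hold", {
  m <- metrics_from_confusion(tibble::tibble(tp = 8, fp = 2, fn = 1, tn = 89))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 8 / 9)
  expect_equal(m$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9))
  expect_equal(m$accuracy, 97 / 100)
  expect_false(m$degenerate)

  none <- metrics_from_confusion(tibble::tibble(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_equal(none$precision, 0)
  expect_true(none$degenerate)

  perfect <- metrics_from_confusion(confusion_from_labels(
    c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)
  ))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1,
                 perfect$accuracy), rep(1, 4))

  # exact rational accuracy on random integer counts
  set.seed(55)
  for (case in 1:50) {
    cts <- as.list(sample(0:20, 4, replace = TRUE))
    names(cts) <- c("tp", "fp", "fn", "tn")
    if (sum(unlist(cts)) == 0) next
    m <- metrics_from_confusion(tibble::as_tibble(cts))
    expect_identical(m$accuracy, (cts$tp + cts$tn) / sum(unlist(cts)))
  }
})

test_that("an extra true positive never hurts precision, recall or accuracy", {
  set.seed(66)
  for (case in 1:50) {
    cm <- tibble::tibble(tp = sample(0:10, 1), fp = sample(0:10, 1),
                         fn = sample(1:10, 1), tn = sample(0:10, 1))
    m0 <- metrics_from_confusion(cm)
    m1 <- metrics_from_confusion(dplyr::mutate(cm, tp = tp + 1, fn = fn - 1))
    expect_gte(m1$precision, m0$precision)
    expect_gte(m1$recall, m0$recall)
    expect_gte(m1$accuracy, m0$accuracy)
  }
})

test_that("the six-method benchmark runs end to end inside the budget", {
  t0 <- Sys.time()
  ds <- generate_dataset(synthetic_spec(n_inliers = 475, contamination = 0.05,
                                        seed = 7))
  report <- run_benchmark(ds)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  m <- tidy(report)
  expect_equal(nrow(m), 6)
  expect_true(all(is.na(m$error)))
  for (col in c("precision", "recall", "f1", "accuracy")) {
    expect_true(all(m[[col]] >= 0 & m[[col]] <= 1))
  }
  expect_lt(elapsed, 60)

  g <- glance(report)
  expect_equal(g$n_methods, 6)
  expect_equal(g$n_failed, 0)
})

test_that("benchmark handles no-outlier data, failures and bad configs", {
  clean <- generate_dataset(synthetic_spec(n_inliers = 80, contamination = 0,
                                           seed = 2))
  rep0 <- run_benchmark(clean, methods = list(
    mahalanobis_envelope = list(confidence = 0.95),
    ssvd_residual = list(rank = 2)
  ))
  expect_true(all(tidy(rep0)$degenerate)) # no positives: recall degenerate

  mixed <- generate_dataset(synthetic_spec(n_inliers = 80,
                                           contamination = 0.05, seed = 2))
  rep1 <- run_benchmark(mixed, methods = list(
    mahalanobis_envelope = list(confidence = 2), # invalid: fails
    ssvd_residual = list(rank = 2)
  ))
  m <- tidy(rep1)
  expect_false(is.na(m$error[m$method == "mahalanobis_envelope"]))
  expect_true(is.na(m$error[m$method == "ssvd_residual"]))

  expect_error(run_benchmark(mixed, methods = list(dbscan = list())),
               regexp = "unknown method")
  unlabeled <- mixed
  unlabeled$labels <- NULL
  expect_error(run_benchmark(unlabeled), class = "agri_config_error")
})

test_that("a detector that flags exactly the truth scores perfectly", {
  ds <- generate_dataset(synthetic_spec(n_inliers = 60, contamination = 0.1,
                                        seed = 9))
  cm <- confusion_from_labels(ds$labels$is_outlier, ds$labels$is_outlier)
  m <- metrics_from_confusion(cm)
  expect_equal(c(m$precision, m$recall, m$f1, m$accuracy), rep(1, 4))
})

test_that("benchmark reports serialize losslessly to JSON", {
  ds <- generate_dataset(synthetic_spec(n_inliers = 80, contamination = 0.05,
                                        seed = 4))
  report <- run_benchmark(ds, methods = list(
    mahalanobis_envelope = list(confidence = 0.95),
    smvod = list(alpha_mix = 0.5)
  ))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_benchmark_report(report, tmp)
  back <- read_benchmark_report(tmp)
  expect_equal(tidy(back), tidy(report))
  expect_equal(back$dataset_summary$n, report$dataset_summary$n)
})

test_that("before/after plots drop exactly the flagged rows", {
  ds <- generate_dataset(synthetic_spec(n_inliers = 95, contamination = 0.05,
                                        seed = 12))
  res <- detect_pca_envelope(ds$table)
  p <- plot_before_after(ds$table, res, c("n", "yield"))
  built <- ggplot2::ggplot_build(p)
  pts <- built$data[[1]]
  n <- nrow(ds$table)
  expect_equal(nrow(pts), n + (n - res$n_flagged))

  f <- withr::local_tempfile(fileext = ".png")
  plot_before_after(ds$table, res, c("n", "yield"), file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  f2 <- withr::local_tempfile(fileext = ".png")
  plot_before_after(ds$table, res, c("n", "yield"), file = f2)
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))

  expect_error(plot_before_after(ds$table, res, c("n", "nope")),
               class = "agri_value_error")
  expect_error(plot_before_after(ds$table, res, c("n", "crop")),
               class = "agri_value_error")
})
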