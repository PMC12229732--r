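#' Before/after scatter of outlier removal
#'
#' Two-panel scatter on a pair of features: the left panel shows every
#' record with flagged rows highlighted, the right panel only the survivors
#' -- the usual way to show how removal clarifies the underlying pattern.
#' Purely presentational; the panels are built from the detector's flags,
#' nothing is recomputed.
#'
#' @param table The record-table tibble the detector ran on.
#' @param result The `outlier_result` for that table.
#' @param feature_pair Character vector of two numeric column names.
#' @param file Optional output path; when given, the figure is written there
#'   (PNG, 18 x 9 cm at 150 dpi) and the path returned invisibly.
#' @return The ggplot object (invisibly when `file` is given).
#' @export
#' @examples
#' tab <- table1_fixture()
#' res <- detect_pca_envelope(tab, features = c("n", "p", "k", "ph", "ec"))
#' plot_before_after(tab, res, c("n", "k"))
plot_before_after <- function(table, result, feature_pair, file = NULL) {
  stopifnot(inherits(result, "outlier_result"))
  if (length(feature_pair) != 2 || !all(feature_pair %in% names(table))) {
    abort("feature_pair must name two columns of the table",
          class = "agri_value_error")
  }
  if (!all(vapply(table[feature_pair], is.numeric, logical(1)))) {
    abort("feature_pair columns must be numeric", class = "agri_value_error")
  }
  flags <- tidy(result)
  df <- dplyr::left_join(
    tibble::tibble(row_id = if ("row_id" %in% names(table)) table$row_id
                   else seq_len(nrow(table)),
                   x = table[[feature_pair[1]]], y = table[[feature_pair[2]]]),
    flags, by = "row_id"
  )
  before <- dplyr::mutate(df, panel = "before removal")
  after <- dplyr::mutate(dplyr::filter(df, !.data$flagged),
                         panel = "after removal")
  both <- dplyr::bind_rows(before, after)
  both$panel <- factor(both$panel, levels = c("before removal", "after removal"))

  p <- ggplot2::ggplot(both, ggplot2::aes(x = .data$x, y = .data$y,
                                          colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.8, size = 1.6) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#d1495b")) +
    ggplot2::labs(x = feature_pair[1], y = feature_pair[2],
                  colour = "flagged",
                  title = paste0(result$method, ": outlier removal")) +
    ggplot2::theme_minimal()

  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 18, height = 9, units = "cm", dpi = 150,
                    device = grDevices::png, bg = "white")
    return(invisible(p))
  }
  p
}
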