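# ggplot2 diagnostics for the main result types.

#' Plot an ordination with group centroids
#'
#' Scatter of the first two ordination axes; when metadata is supplied the
#' points are coloured by group and the group centroids (the anchors of
#' the offset statistic) are drawn as crosses.
#'
#' @param object An `ms_ordination` object.
#' @param metadata Optional tibble with `sample_id` and `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_ordination
#' @export
autoplot.ms_ordination <- function(object, metadata = NULL, ...) {
  df <- tidy(object, metadata)
  labs_xy <- sprintf("PCo%d (%.1f%%)", 1:2,
                     100 * object$proportion_explained[1:2])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PCo1, .data$PCo2))
  if (!is.null(metadata) && "group" %in% names(df)) {
    cen <- df |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(PCo1 = mean(.data$PCo1), PCo2 = mean(.data$PCo2),
                       .groups = "drop")
    p <- p +
      ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
      ggplot2::geom_point(data = cen,
                          ggplot2::aes(colour = .data$group),
                          shape = 4, size = 4, stroke = 1.5)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::labs(x = labs_xy[1], y = labs_xy[2]) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of a GM offset test
#'
#' Histogram of the permuted centroid distances with the observed offset
#' marked.
#'
#' @param object An `ms_offset_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_offset_test
#' @export
autoplot.ms_offset_test <- function(object, ...) {
  df <- tibble(null = object$null_distribution)
  ggplot2::ggplot(df, ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$gm_offset, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(
      x = "centroid distance under permuted labels",
      y = "count",
      title = sprintf("%s vs %s: GM offset = %.3f, p = %.3g",
                      object$group_a, object$group_b, object$gm_offset,
                      object$permutation_p)) +
    ggplot2::theme_minimal()
}

#' Bar plot of Firmicutes/Bacteroidota ratios
#'
#' @param fb Output of [fb_ratio()].
#' @return A ggplot object.
#' @export
plot_fb_ratio <- function(fb) {
  xvar <- if ("group" %in% names(fb)) "group" else "sample_id"
  ggplot2::ggplot(fb, ggplot2::aes(.data[[xvar]], .data$fb_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Firmicutes / Bacteroidota") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
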