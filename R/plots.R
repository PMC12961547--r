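#' Bar chart of peak orthology classes
#'
#' @param summary Output of [peak_class_summary()] or [class_percentages()],
#'   or a named list of them (one facet per direction).
#' @return A ggplot object.
#' @export
plot_peak_classes <- function(summary) {
  if (!is.data.frame(summary)) {
    summary <- purrr::imap(summary, function(s, nm) mutate(s, direction = nm)) |>
      list_rbind()
  } else {
    summary$direction <- "peaks"
  }
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$klass, y = .data$percent,
                               fill = .data$klass)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%% (n=%d)",
                                                    .data$percent, .data$n)),
                       vjust = -0.3, size = 3) +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = NULL, y = "% of classified peaks") +
    ggplot2::theme_minimal()
}

#' Stacked peak-class composition per regulation type
#'
#' @param composition Output of [class_composition_by_type()].
#' @return A ggplot object.
#' @export
plot_class_composition <- function(composition) {
  ggplot2::ggplot(filter(composition, !is.na(.data$prop)),
                  ggplot2::aes(x = factor(.data$type), y = .data$prop,
                               fill = .data$klass)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "regulation type", y = "proportion of linked peaks",
                  fill = "peak class") +
    ggplot2::theme_minimal()
}

#' Heatmap of a binned signal matrix
#'
#' @param mat Output of [signal_matrix()].
#' @return A ggplot object.
#' @export
plot_signal_matrix <- function(mat) {
  bins <- attr(mat, "bin_start")
  df <- tibble(site = rep(seq_len(nrow(mat)), times = ncol(mat)),
               bin = rep(bins, each = nrow(mat)),
               density = as.vector(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$site,
                                   fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "distance from summit (bp)", y = "site (by total signal)",
                  fill = "RPM") +
    ggplot2::theme_minimal()
}

#' @rdname magnitude_test
#' @param object A `cisdiv_magnitude`.
#' @export
autoplot.cisdiv_magnitude <- function(object, ...) {
  typed <- object$typed
  df <- bind_rows(
    tibble(allele = "A", type = typed$type, mag = abs(typed$log2fc_a)),
    tibble(allele = "B", type = typed$type, mag = abs(typed$log2fc_b))
  ) |> filter(.data$type %in% c(1L, 3L, 4L))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$type), y = .data$mag)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~allele) +
    ggplot2::labs(x = "regulation type", y = "|log2 fold change|") +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object A `cisdiv_report`.
#' @param ... Unused.
#' @export
autoplot.cisdiv_report <- function(object, ...) {
  plot_peak_classes(object$peak_class_summary)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
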