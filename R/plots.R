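# ggplot2 figures for the three result types. Distributions carry a
# `set` column, so one call comparing several sets produces dodged bars
# in the style of the usual phylostratigraphy figures.

#' @export
autoplot.pai_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$rank), y = .data$percent, fill = .data$set
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single")) +
    ggplot2::labs(
      x = "PAI (divergence stage rank)",
      y = "Genes (%)",
      fill = NULL,
      title = "Phylostratigraphic age distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.di_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
    y = .data$percent, fill = .data$set
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      width = (object$bin_end[1] - object$bin_start[1]) * 0.9) +
    ggplot2::labs(
      x = "Divergence index (mean pairwise dN/dS)",
      y = "Genes (%)",
      fill = NULL,
      title = "Divergence-index distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::mutate(
      comparison = paste0(.data$set, " vs ", .data$background,
                          "\n", .data$category)
    ) |>
    tidyr::pivot_longer(c("observed", "expected"),
                        names_to = "kind", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$comparison, y = .data$count, fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "Gene count", fill = NULL,
      title = "Observed vs expected category counts"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
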