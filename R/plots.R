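#' Predicted versus measured proportions
#'
#' Scatter of predicted against reference proportions, one point per
#' (unit, cell type), coloured by cell type, with the identity line
#' and the pooled correlation and rmse in the subtitle.
#'
#' @param pred,truth `proportion_tbl` objects sharing cell types and
#'   units.
#' @param match_on unit key column.
#' @return a ggplot.
#' @export
plot_proportions <- function(pred, truth, match_on = "unit_id") {
  pl <- tidy(pred)
  tl <- tidy(truth)[, c(match_on, "cell_type", "proportion")]
  names(tl)[names(tl) == "proportion"] <- "truth"
  df <- dplyr::inner_join(pl, tl, by = c(match_on, "cell_type"))
  metrics <- compare_proportions(pred, truth, match_on = match_on)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$proportion,
                                   colour = .data$cell_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "measured proportion", y = "predicted proportion",
      colour = "cell type",
      subtitle = sprintf("cor = %.3f, rmse = %.3f",
                         metrics$cor, metrics$rmse)
    ) +
    ggplot2::theme_minimal()
}

#' Mean Ratio against one-vs-all fold change
#'
#' One panel per cell type, each gene a point; the top-ranked Mean
#' Ratio genes are highlighted. Useful for seeing that the two marker
#' statistics agree on the best genes while Mean Ratio penalises
#' expression in the runner-up type.
#'
#' @param stats a [marker_stats()] tibble.
#' @param top_n number of top-ranked genes to highlight per type.
#' @return a ggplot.
#' @export
plot_marker_stats <- function(stats, top_n = 25) {
  df <- mutate(stats,
               ratio_plot = pmin(.data$mean_ratio,
                                 max(.data$mean_ratio[
                                   is.finite(.data$mean_ratio)])),
               top = .data$rank_ratio <= top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC_1vall,
                                   y = .data$ratio_plot,
                                   colour = .data$top)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~cell_type, scales = "free") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d95f02",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "one-vs-all logFC", y = "Mean Ratio",
                  colour = sprintf("top %d by Mean Ratio", top_n)) +
    ggplot2::theme_minimal()
}

#' Composition bar plot
#'
#' Stacked per-unit cell-type composition bars.
#'
#' @param props a `proportion_tbl`.
#' @return a ggplot.
#' @export
plot_composition <- function(props) {
  df <- tidy(props)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$unit_id,
                                   y = .data$proportion,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Across-replicate dispersion of a resampling experiment
#'
#' @param result a [equal_proportion_resample()] result.
#' @return a ggplot of per-cell-type across-replicate standard
#'   deviations.
#' @export
plot_resample_dispersion <- function(result) {
  ggplot2::ggplot(result$dispersion,
                  ggplot2::aes(x = .data$cell_type, y = .data$sd)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "cell type",
                  y = "across-replicate sd of estimated proportion") +
    ggplot2::theme_minimal()
}
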