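#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot differential-abundance effect sizes
#'
#' Horizontal bar chart of significant taxa per covariate, coloured by
#' enrichment direction, mirroring the usual coefficient plots of
#' multivariable differential-abundance reports.
#'
#' @param object A `gc_da` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_da <- function(object, ...) {
  df <- effect_plot_table(object)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no significant taxa") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$coefficient,
    y = stats::reorder(.data$taxon, abs(.data$coefficient)),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$covariate), scales = "free_y") +
    ggplot2::labs(x = "coefficient (log2 effect on relative abundance)",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PERMANOVA variance decomposition
#'
#' Per-term R-squared bars with significance asterisks on terms with
#' permutation p below `alpha`.
#'
#' @param object A `gc_permanova` result.
#' @param alpha Significance level used for labelling (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_permanova <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df <- df[df$term != "Residual", , drop = FALSE]
  df$label <- ifelse(!is.na(df$p.value) & df$p.value < alpha, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term, .data$R2),
                                   y = .data$R2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(R^2)) +
    ggplot2::theme_minimal()
}

#' Boxplots of an outcome by a clinicopathological variable
#'
#' @param data A tibble with the outcome and grouping columns (e.g. the
#'   per-sample alpha-diversity/abundance table from the pipeline).
#' @param outcome,group Column names (strings).
#' @param log_y Log10 y axis (default TRUE, the usual scale for
#'   microbial abundance).
#' @return A ggplot object.
#' @export
plot_outcome_by_group <- function(data, outcome, group, log_y = TRUE) {
  df <- data[!is.na(data[[group]]) & !is.na(data[[outcome]]), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]],
                                        y = .data[[outcome]],
                                        fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.shape = 21, alpha = 0.8) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
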