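#' Plot a degree distribution with its power-law fit
#'
#' Log-log scatter of degree frequency with the least-squares line of a
#' [fit_power_law()] object.
#'
#' @param object A `powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$log_k, y = .data$log_n)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(
      x = "log degree", y = "log frequency",
      title = sprintf("Power-law fit: slope = %.3f, R² = %.3f",
                      object$slope, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot topological metrics by node type
#'
#' Boxplots of a node metric split by node type, the visual companion of
#' [compare_metric_by_type()].
#'
#' @param metrics A tibble from [node_metrics()].
#' @param metric Metric column name (`"degree"`, `"bc"`, `"tc"`).
#' @return A ggplot object.
#' @export
plot_metric_by_type <- function(metrics, metric = "degree") {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$type, y = .data[[metric]],
                               fill = .data$type)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot regulating proportions of hub lncRNAs
#'
#' Stacked proportion bars of disease-gene classes regulated by each hub
#' lncRNA.
#'
#' @param props A tibble from [regulating_proportions()].
#' @return A ggplot object.
#' @export
plot_regulating_proportions <- function(props) {
  long <- tidyr::pivot_longer(
    select(props, "lncrna", "p_diabetes", "p_dr", "p_common"),
    cols = -"lncrna", names_to = "class", values_to = "proportion")
  long$class <- factor(long$class, levels = c("p_diabetes", "p_dr",
                                              "p_common"),
                       labels = c("diabetes", "DR", "common"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lncrna,
                                     y = .data$proportion,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "regulating proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot an enrichment table
#'
#' Dot plot of the top enriched sets: overlap size against set, coloured by
#' adjusted p-value.
#'
#' @param enrichment A tibble from [enrich()].
#' @param top Number of sets shown (default 10).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 10) {
  df <- head(enrichment, top)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$overlap, y = .data$set,
                                   colour = .data$p_adjust,
                                   size = .data$overlap)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "red", high = "blue") +
    ggplot2::labs(x = "overlap", y = NULL, colour = "BH p",
                  size = "overlap") +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential expression
#'
#' @param de A tibble from [differential_expression()].
#' @param p_cutoff,fc_cutoff Thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_cutoff = 0.05, fc_cutoff = 1.5) {
  df <- filter(de, is.finite(.data$log2_fc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_cutoff), log2(fc_cutoff)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}
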