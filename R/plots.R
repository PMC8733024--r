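#' Plot posterior variance partitions
#'
#' Violin plot of the posterior draws of each variance component by group,
#' with optional true-value crossbars, in the style used for cohort-level
#' breeding and genomic analyses.
#'
#' @param object A `partition_posterior`.
#' @param truth Optional tibble with `group`, `component`, `true_value`.
#' @param components Components to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.partition_posterior <- function(object, truth = NULL,
                                         components = c("total", "genic",
                                                        "within_ld",
                                                        "between_ld"),
                                         ...) {
  df <- dplyr::filter(tibble::as_tibble(object), is.na(.data$chromosome),
                      .data$component %in% components)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", colour = "grey40", scale = "width") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "variance (1/n)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(truth)) {
    tr <- dplyr::filter(truth, .data$component %in% components)
    p <- p + ggplot2::geom_point(data = tr,
                                 ggplot2::aes(y = .data$true_value),
                                 shape = 3, size = 2, colour = "black")
  }
  p
}

#' Plot temporal trends of posterior variance summaries
#'
#' Posterior-mean lines with quantile ribbons over years, one panel per
#' component, coloured by breeding stage; true values, when given, are drawn
#' as solid lines.
#'
#' @param summary Output of [summarize_posterior()] with `stage` and `year`
#'   columns (join them from [sim_groups()] if needed).
#' @param truth Optional tibble with `stage`, `year`, `component`,
#'   `true_value`.
#' @return A ggplot object.
#' @export
plot_temporal_trends <- function(summary, truth = NULL) {
  p <- ggplot2::ggplot(summary,
                       ggplot2::aes(x = .data$year, y = .data$mean,
                                    colour = .data$stage,
                                    fill = .data$stage)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q_low,
                                      ymax = .data$q_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "year", y = "variance (1/n)") +
    ggplot2::theme_minimal()
  if (!is.null(truth))
    p <- p + ggplot2::geom_line(data = truth,
                                ggplot2::aes(y = .data$true_value),
                                linetype = "solid")
  p
}
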