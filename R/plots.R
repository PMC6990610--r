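#' Plot per-level observed means of the orthogonal screen
#'
#' The optimal-level view: observed attribute means at each level of each
#' design factor, one panel per factor, with the per-factor F statistic and
#' significance stars in the panel strip.
#'
#' @param x A `main_effects` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.main_effects <- function(x, ...) {
  lm <- x$level_means
  lab <- setNames(
    sprintf("%s (F=%.2f%s)", x$anova$factor, x$anova$statistic, x$anova$stars),
    x$anova$factor
  )
  ggplot2::ggplot(lm, ggplot2::aes(x = .data$level, y = .data$mean, group = 1)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~factor, scales = "free_x",
                        labeller = ggplot2::as_labeller(lab)) +
    ggplot2::labs(x = "factor level", y = paste("mean", x$attribute)) +
    ggplot2::theme_bw()
}

#' Distribution of attributes across orthogonal tests
#'
#' Boxplots of one attribute per test id, a quick view of a
#' [run_orthogonal()] result table.
#'
#' @param results A [run_tests()] result tibble.
#' @param attribute Attribute column name.
#' @return A ggplot object.
#' @export
plot_attribute_distribution <- function(results, attribute) {
  ok <- results[results$status == "ok", , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$test_id, y = .data[[attribute]])) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = attribute) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
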