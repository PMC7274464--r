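#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ROC sweep
#'
#' TPR against FPR over the threshold grid, with the no-discrimination
#' diagonal and the maximal-informedness point highlighted.
#'
#' @param object A `roc_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_sweep <- function(object, ...) {
  best <- object[which.max(object$informedness), ]
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac", size = 1.6) +
    ggplot2::geom_point(data = best, colour = "#b2182b", size = 2.6) +
    ggplot2::annotate(
      "text", x = best$fpr, y = best$tpr, vjust = -1, hjust = -0.05,
      label = sprintf("h = %.2f, J = %.2f", best$h, best$informedness),
      size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Threshold sweep ROC") +
    ggplot2::theme_minimal()
}

#' Plot per-sample deregulation burden
#'
#' Stacked per-sample percentages of up- and down-regulated genes.
#'
#' @param object A `dereg_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dereg_calls <- function(object, ...) {
  burden <- sample_burden(object)
  long <- tidyr::pivot_longer(
    burden[, c("sample", "pct_up", "pct_down")],
    cols = c("pct_up", "pct_down"),
    names_to = "direction", values_to = "pct")
  long$direction <- factor(long$direction, levels = c("pct_up", "pct_down"),
                           labels = c("up", "down"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$pct,
                                     fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac")) +
    ggplot2::labs(x = NULL, y = "% of genes", fill = NULL,
                  title = "Per-sample deregulation burden") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom rlang .data
NULL
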