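#' Heatmaps of a fitted matrix-normal model
#'
#' Side-by-side tile plots of the low-order mean matrix and the high-order
#' covariance factor.
#'
#' @param object An `mvnd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mvnd_fit <- function(object, ...) {
  td <- tidy(object)
  td$role <- factor(td$role, levels = c("mean", "factor"),
                    labels = c("low-order (mean)", "high-order (factor)"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~role, scales = "free") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Per-fold metric distribution of a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object (one box per metric over folds and repeats).
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[, c("rep", "fold", "acc", "tpr", "tnr", "ppv", "npv")],
    c("acc", "tpr", "tnr", "ppv", "npv"), names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "outer-fold value") +
    ggplot2::theme_minimal()
}

#' Bar chart of sub-network contribution rates
#'
#' @param result A `cv_result`.
#' @param provenance Optional provenance override (see
#'   [contribution_trace()]).
#' @return A ggplot object.
#' @export
plot_contributions <- function(result, provenance = result$provenance) {
  contrib <- contribution_trace(result, provenance)
  contrib$network <- factor(contrib$network, levels = contrib$network)
  ggplot2::ggplot(contrib, ggplot2::aes(x = .data$network, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "sub-network", y = "contribution rate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
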