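#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Real-vs-synthetic moment agreement plot
#'
#' Scatter of per-column synthetic versus real mean and standard deviation;
#' well-matched tables fall on the diagonal.
#'
#' @param object A `sleepaug_gan_validation`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sleepaug_gan_validation <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$columns,
    c("mean_real", "mean_fake", "std_real", "std_fake"),
    names_to = c("stat", "which"), names_sep = "_")
  d <- tidyr::pivot_wider(d, names_from = "which", values_from = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$real, y = .data$fake,
                                  colour = .data$pass)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stat, scales = "free") +
    ggplot2::labs(x = "real data", y = "synthetic data",
                  title = "Column moments: real vs synthetic")
}

#' Evaluation-metric bar chart
#'
#' @param object A `sleepaug_eval` report.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sleepaug_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Classifier evaluation")
}

#' Cross-validation fold accuracies
#'
#' @param object A `sleepaug_cv`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sleepaug_cv <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$fold),
                                       y = .data$accuracy)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_hline(yintercept = mean(object$accuracy), linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "accuracy",
                  title = sprintf("%s cross-validation (%s)",
                                  attr(object, "scheme"), object$model[1]))
}

#' Band-wise feature distributions by class
#'
#' Violin plots of one of the nine features across the five bands, split by
#' class - the visual check that a planted or physiological class contrast
#' survives the processing chain.
#'
#' @param features Feature tibble from [extract_features()].
#' @param feature One of the nine feature names (default `"band_power"`).
#' @return A ggplot.
#' @export
plot_band_features <- function(features, feature = "band_power") {
  feature <- match.arg(feature, FEATURE_NAMES)
  cols <- paste(BAND_NAMES, feature, sep = "_")
  d <- tidyr::pivot_longer(features[c(cols, "label")], -"label",
                           names_to = "band", values_to = "value")
  d$band <- factor(sub(paste0("_", feature), "", d$band), levels = BAND_NAMES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$value,
                                  fill = .data$label)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(0.8), scale = "width") +
    ggplot2::labs(y = feature, x = NULL,
                  title = sprintf("%s by band and class", feature))
}
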