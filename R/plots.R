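# ggplot2 views of the main result types.

#' Plot splicing-ratio trajectories
#'
#' One line per gene over the nascent time points, with the steady-state
#' ratio drawn as a point at the right margin.
#'
#' @param estimates Tibble with `gene_id`, `time`, `ratio`.
#' @param ss_position x-axis position at which to draw the steady state
#'   (default 7 min).
#' @return A ggplot object.
#' @export
plot_splicing_trajectories <- function(estimates, ss_position = 7) {
  assert_columns(estimates, c("gene_id", "time", "ratio"), "estimates")
  nasc <- filter(estimates, is.finite(.data$time))
  ss <- filter(estimates, is.infinite(.data$time)) |>
    mutate(time = ss_position)
  ggplot2::ggplot(nasc, ggplot2::aes(x = .data$time, y = .data$ratio,
                                     group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(data = ss, shape = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "labeling time (min; open circles = steady state)",
                  y = "splicing ratio R = mRNA / (mRNA + pre-mRNA)")
}

#' Plot an estimator-variance benchmark
#'
#' @param bench Tibble from [estimator_benchmark()].
#' @return A ggplot object (variance vs coverage, one line per estimator).
#' @export
plot_estimator_benchmark <- function(bench) {
  assert_columns(bench, c("coverage", "estimator", "variance"), "bench")
  ggplot2::ggplot(bench, ggplot2::aes(x = .data$coverage, y = .data$variance,
                                      colour = .data$estimator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reads per gene", y = "empirical variance of the estimate")
}

#' @describeIn nb_classifier_cv ROC curve of the pooled out-of-fold scores.
#' @param object A `tu_nb_cv` object.
#' @param ... Unused.
#' @export
autoplot.tu_nb_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' @describeIn rf_regression Observed vs out-of-bag predicted scatterplot.
#' @param object A `tu_rf` object.
#' @param ... Unused.
#' @export
autoplot.tu_rf <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted_oob)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed", y = "out-of-bag predicted",
                  title = sprintf("r = %.3f", object$r))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
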