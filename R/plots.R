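#' Plot a replicated study's validation results
#'
#' `type = "risk_accuracy"` shows the accuracy of predicted total risk for
#' the separated (novel) and non-separated (conventional) approaches per
#' model family and scenario; `"gebv_accuracy"` shows GEBV accuracies per
#' family/variant/dataset; `"bias"` shows the calibration slopes with the
#' reference line at 1.
#'
#' @param object a `risk_study`.
#' @param type which panel to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot risk_study
#' @export
autoplot.risk_study <- function(object,
                                type = c("risk_accuracy", "gebv_accuracy",
                                         "bias"),
                                ...) {
  type <- match.arg(type)
  s <- object$summary
  if (type == "risk_accuracy") {
    d <- dplyr::filter(s, .data$metric == "risk_accuracy",
                       .data$variant == 1L)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$mean,
                                         fill = .data$approach)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "risk-prediction accuracy (r)", x = NULL,
                    fill = NULL)
  } else if (type == "gebv_accuracy") {
    d <- dplyr::filter(s, .data$metric == "gebv_accuracy")
    p <- ggplot2::ggplot(
      d, ggplot2::aes(x = .data$family, y = .data$mean,
                      fill = interaction(.data$dataset, .data$variant))) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "GEBV accuracy (r with TBV)", x = NULL,
                    fill = "dataset.variant")
  } else {
    d <- dplyr::filter(s, .data$metric == "bias_slope")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$family, y = .data$mean,
                                         fill = .data$approach)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(y = "slope of observed on predicted", x = NULL,
                    fill = NULL)
  }
  if (any(!is.na(d$se)))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2)
  p + ggplot2::facet_wrap(~scenario)
}
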