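#' Plot an HBI fit
#'
#' Bar panels of estimated model frequencies and protected exceedance
#' probabilities (falling back to exceedance probabilities when the null run
#' was skipped).
#'
#' @param object An `hbi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hbi_fit
#' @export
autoplot.hbi_fit <- function(object, ...) {
  df <- tidy(object, type = "frequency")
  df$selection <- if (all(is.na(df$pxp))) df$xp else df$pxp
  long <- tidyr::pivot_longer(
    df[, c("model", "frequency", "selection")],
    cols = c("frequency", "selection"),
    names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, c("frequency", "selection"),
                        c("model frequency", "protected exceedance prob."))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Convergence diagnostics
#'
#' Traces of the normalized parameter change `dhat` (log scale) and the
#' variational lower bound across iterations.
#'
#' @param fit An `hbi_fit`.
#' @return A ggplot object.
#' @export
plot_convergence <- function(fit) {
  tr <- fit$trace
  tr <- tr[is.finite(tr$dhat), ]
  long <- tidyr::pivot_longer(tr, c("dhat", "lower_bound"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attribution ROC curve
#'
#' @param roc Output of [attribution_roc()].
#' @return A ggplot object.
#' @export
plot_attribution_roc <- function(roc) {
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = 2, color = "grey") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false attribution rate", y = "true attribution rate",
                  subtitle = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}
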