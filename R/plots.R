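#' Plot ROC and PR curves of an evaluation
#'
#' @param object A `ddi_eval`.
#' @param ... Unused.
#' @return A ggplot object with one panel per curve.
#' @export
autoplot.ddi_eval <- function(object, ...) {
  d <- tidy(object)
  d$curve <- factor(d$curve, c("roc", "pr"), c("ROC", "Precision-recall"))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(
      x = "FPR (ROC) / recall (PR)", y = "TPR (ROC) / precision (PR)",
      title = sprintf("%s prediction: AUC = %.3f, AUPR = %.3f",
                      object$protocol, object$auc, object$aupr)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-round cross-validation performance
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object showing per-round AUC and AUPR.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$rounds, c("auc", "aupr"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(dplyr::filter(d, !.data$skipped),
                  ggplot2::aes(.data$round, .data$value, colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "round", y = NULL, colour = "round kind",
                  title = sprintf("%s %s CV: mean AUC %.3f, mean AUPR %.3f",
                                  toupper(object$scheme), object$protocol,
                                  object$auc, object$aupr)) +
    ggplot2::theme_minimal()
}

#' Plot the latent-factor tuning curve
#'
#' @param object A `tmfuf_tuning`.
#' @param ... Unused.
#' @return A ggplot object of mean AUC against the number of latent factors.
#' @export
autoplot.tmfuf_tuning <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(.data$ncomp, .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_ncomp, linetype = 2) +
    ggplot2::labs(x = "latent factors (L)", y = "mean AUC (binary CV1)",
                  title = sprintf("best L = %d", object$best_ncomp)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of projection-matrix entries
#'
#' @param object A `theta_summary`.
#' @param ... Unused.
#' @return A ggplot histogram of the upper-triangle entries of the
#'   projection matrix, with the significance thresholds marked.
#' @export
autoplot.theta_summary <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_high[1] - h$bin_low[1]) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$threshold,
                        linetype = 2, colour = "red") +
    ggplot2::labs(x = "projection entry value", y = "count",
                  title = sprintf("%d significant entries (|theta| > %g)",
                                  object$n_significant_positive +
                                    object$n_significant_negative,
                                  object$threshold)) +
    ggplot2::theme_minimal()
}
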