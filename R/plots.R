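# ggplot2 views of the result objects

#' Plot ROC and precision-recall curves of a cross-validation
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot with ROC and PR panels.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- bind_rows(
    tibble(panel = "ROC", x = object$roc$fpr, y = object$roc$tpr),
    tibble(panel = "Precision-recall", x = object$pr$recall,
           y = object$pr$precision)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step(linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = "false positive rate / recall",
      y = "true positive rate / precision",
      title = sprintf("Leave-one-out cross-validation (AUC = %.3f)",
                      object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of predicted vs original weighted degrees
#'
#' @param object A `degree_comparison`.
#' @param ... Unused.
#' @return A ggplot boxplot.
#' @export
autoplot.degree_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$weighted_degree)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 15) +
    ggplot2::labs(x = NULL, y = "weighted degree",
                  subtitle = sprintf("rank-sum p = %.3g", object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Boxplot of normalized weighted degree by conservation status
#'
#' @param object A `module_comparison`.
#' @param ... Unused.
#' @return A ggplot boxplot faceted by species.
#' @export
autoplot.module_comparison <- function(object, ...) {
  ggplot2::ggplot(object$partition,
                  ggplot2::aes(x = .data$status,
                               y = .data$normalized_weighted_degree)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 15) +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "normalized weighted degree") +
    ggplot2::theme_minimal()
}
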