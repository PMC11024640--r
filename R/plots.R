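#' Plot a ROC curve
#'
#' @param object An `lnc_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.lnc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `lnc_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot with one point per fold and metric.
#' @export
autoplot.lnc_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[c("fold", "sensitivity", "specificity", "accuracy",
                   "precision", "f1")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7,
                         colour = "#2c7fb8") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Value",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}

#' Bar chart of positional lncRNA classes
#'
#' @param classification A [classify_positions()] (or pipeline) result.
#' @return A ggplot.
#' @export
plot_lnc_classes <- function(classification) {
  counts <- dplyr::count(classification, .data$lnc_class)
  counts$lnc_class <- factor(counts$lnc_class, levels = LNC_CLASSES)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$lnc_class, y = .data$n)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = NULL, y = "lncRNAs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.lnc_model <- function(object, ...) {
  if (object$spec$kind != "logistic") {
    stop("autoplot is available for logistic models only", call. = FALSE)
  }
  coefs <- tidy.lnc_model(object)
  coefs <- coefs[coefs$term != "(intercept)", , drop = FALSE]
  ggplot2::ggplot(coefs, ggplot2::aes(x = stats::reorder(.data$term,
                                                         .data$estimate),
                                      y = .data$estimate)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Weight (z-scored feature scale)") +
    ggplot2::theme_minimal()
}
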