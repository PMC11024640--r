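#' Tidy a trained classifier
#'
#' For a logistic model, one row per model term with its weight on the
#' z-scored feature scale; for an SVM, one row per feature with the Platt
#' calibration summarised in [glance.lnc_model()].
#'
#' @param x An `lnc_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lnc_model <- function(x, ...) {
  if (x$spec$kind == "logistic") {
    tibble(term = c("(intercept)", x$feature_names),
           estimate = c(x$params$intercept, unname(x$params$weights)))
  } else {
    tibble(term = x$feature_names,
           n_support_vectors = x$params$svm$tot.nSV)
  }
}

#' @rdname tidy.lnc_model
#' @export
glance.lnc_model <- function(x, ...) {
  tibble(kind = x$spec$kind, schema = x$spec$schema,
         n_features = length(x$feature_names),
         n_dropped = length(x$dropped_features),
         n_train = x$n_train, threshold = x$threshold,
         lambda = x$spec$lambda, cost = x$spec$cost)
}

#' Tidy cross-validation results
#'
#' @param x An `lnc_cv` from [cross_validate()].
#' @param ... Unused.
#' @return `tidy()`: the per-fold metric tibble; `glance()`: the one-row
#'   pooled metrics.
#' @export
tidy.lnc_cv <- function(x, ...) x$folds

#' @rdname tidy.lnc_cv
#' @export
glance.lnc_cv <- function(x, ...) {
  dplyr::bind_cols(tibble(k = x$k), x$pooled)
}

#' Tidy a ROC curve
#'
#' @param x An `lnc_roc` from [roc_curve()].
#' @param ... Unused.
#' @return `tidy()`: the (threshold, fpr, tpr) points; `glance()`: one row
#'   with `auc`, `n_pos`, `n_neg`.
#' @export
tidy.lnc_roc <- function(x, ...) x$points

#' @rdname tidy.lnc_roc
#' @export
glance.lnc_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}
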