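#' Confusion counts for lncRNA/mRNA calls
#'
#' lncRNA is the positive class: TP = lncRNA called lncRNA, TN = mRNA called
#' mRNA, FP = mRNA called lncRNA, FN = lncRNA called mRNA.
#'
#' @param truth,predicted Equal-length vectors over `{"lncRNA", "mRNA"}`.
#' @return One-row tibble with columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted labels differ in length", call. = FALSE)
  }
  ok <- c("lncRNA", "mRNA")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'lncRNA' or 'mRNA'", call. = FALSE)
  }
  tibble(TP = sum(truth == "lncRNA" & predicted == "lncRNA"),
         TN = sum(truth == "mRNA" & predicted == "mRNA"),
         FP = sum(truth == "mRNA" & predicted == "lncRNA"),
         FN = sum(truth == "lncRNA" & predicted == "mRNA"))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, precision `TP/(TP+FP)` and the F1-score
#' `2*precision*sensitivity/(precision+sensitivity)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0; F1 is
#' defined only when precision and sensitivity are defined and their sum is
#' positive.
#'
#' @param cc A [confusion()] result (or any one-row data frame / named vector
#'   with `TP`, `TN`, `FP`, `FN`).
#' @return One-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, `f1`.
#' @export
metrics <- function(cc) {
  cc <- as.list(cc)
  tp <- cc$TP; tn <- cc$TN; fp <- cc$FP; fn <- cc$FN
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  tibble(sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / total, precision = prec, f1 = f1)
}

#' ROC curve and AUC
#'
#' Thresholds are the unique scores in descending order with a `+Inf`
#' sentinel; tied scores are grouped at one threshold. The AUC is computed by
#' trapezoidal integration over (FPR, TPR), which equals the Mann-Whitney
#' pairwise statistic `P(score_pos > score_neg) + 0.5 * P(tie)`.
#'
#' @param scores Finite numeric scores (larger = more lncRNA-like).
#' @param truth Labels over `{"lncRNA", "mRNA"}`; both classes must occur.
#' @return An `lnc_roc` object: list with `points` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.character(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  y <- as_binary_labels(truth)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  grp_last <- cumsum(rle(s)$lengths)  # last index of each tied score group
  tp <- cumsum(yy)[grp_last]
  fp <- cumsum(1 - yy)[grp_last]
  pts <- tibble(threshold = c(Inf, s[grp_last]),
                fpr = c(0, fp / n_neg),
                tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "lnc_roc")
}

#' @export
print.lnc_roc <- function(x, ...) {
  cat("<lnc_roc> ", nrow(x$points), " points, AUC = ",
      format(x$auc, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Evaluate classifier calls against truth labels
#'
#' @param calls Tibble with `transcript_id`, `label`, and optionally a score
#'   column (`score` or `score_a`; the ensemble's `score_a`/`score_b` are
#'   combined by their minimum, matching the intersection rule).
#' @param truth Tibble with `transcript_id`, `label`.
#' @return One-row tibble: confusion counts, the five metrics, and `auc` when
#'   scores are available.
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(all(c("transcript_id", "label") %in% names(calls)),
            all(c("transcript_id", "label") %in% names(truth)))
  m <- dplyr::inner_join(calls, truth, by = "transcript_id",
                         suffix = c("_pred", "_true"))
  if (nrow(m) == 0L) stop("no transcripts in common", call. = FALSE)
  cc <- confusion(m$label_true, m$label_pred)
  out <- dplyr::bind_cols(cc, metrics(cc))
  sc <- if ("score" %in% names(m)) {
    m$score
  } else if (all(c("score_a", "score_b") %in% names(m))) {
    pmin(m$score_a, m$score_b)
  } else if ("score_a" %in% names(m)) {
    m$score_a
  } else NULL
  if (!is.null(sc) && length(unique(m$label_true)) == 2L) {
    out$auc <- roc_curve(sc, m$label_true)$auc
  }
  out
}
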