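#' Specify a coding-potential classifier
#'
#' @param kind `"logistic"` (L2-penalised logistic regression, the CPAT-style
#'   model) or `"svm_rbf"` (soft-margin SVM with an RBF kernel and Platt
#'   probability calibration, the PLEK/LncFinder-style model).
#' @param schema Feature schema the model consumes (see [extract_features()]).
#' @param lambda L2 penalty strength for the logistic model (`>= 0`).
#' @param cost,gamma SVM cost parameter `C > 0` and RBF width `gamma > 0`;
#'   `gamma = NULL` uses `1 / n_features` on the standardized features.
#' @param threshold_policy `"fixed_0.5"` or `"youden_cv"` (Youden-J optimal
#'   cutoff chosen on seeded 3-fold out-of-fold scores).
#' @return A `model_spec` list.
#' @export
model_spec <- function(kind = c("logistic", "svm_rbf"),
                       schema = c("cpat", "plek", "lncfinder-lite"),
                       lambda = 0, cost = 1, gamma = NULL,
                       threshold_policy = c("fixed_0.5", "youden_cv")) {
  kind <- match.arg(kind)
  schema <- match.arg(schema)
  stopifnot(lambda >= 0, cost > 0, is.null(gamma) || gamma > 0)
  structure(list(kind = kind, schema = schema, lambda = lambda,
                 cost = cost, gamma = gamma,
                 threshold_policy = match.arg(threshold_policy)),
            class = "model_spec")
}

# L2-penalised logistic regression by damped Newton (IRLS); intercept
# unpenalised; converges to gradient-infinity-norm <= tol when the optimum
# is finite (separable data with lambda = 0 saturates at maxit instead).
fit_logistic_irls <- function(Z, y, lambda = 0, tol = 1e-8, maxit = 100L) {
  Z1 <- cbind(`(intercept)` = 1, Z)
  p <- ncol(Z1)
  pen <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(Z1 %*% b)
    # numerically stable log(1 + exp(eta))
    lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    -sum(y * eta - lse) + 0.5 * sum(pen * b^2)
  }
  cur <- obj(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(Z1 %*% beta)
    mu <- plogis(eta)
    g <- drop(crossprod(Z1, y - mu)) - pen * beta
    if (max(abs(g)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z1, Z1 * w) + diag(pen + 1e-12, p)
    step <- drop(solve(H, g))
    # damped update: halve until the penalised deviance does not increase
    t <- 1
    repeat {
      cand <- beta + t * step
      val <- obj(cand)
      if (val <= cur + 1e-12 || t < 1e-8) break
      t <- t / 2
    }
    beta <- beta + t * step
    cur <- obj(beta)
  }
  list(intercept = beta[[1]], weights = beta[-1],
       gradient_norm = max(abs(g)), iterations = it)
}

#' Train a coding-potential classifier on a labeled feature set
#'
#' Features are z-scored with training statistics (constant features are
#' dropped and recorded). The logistic model maximises the L2-penalised
#' Bernoulli log-likelihood by damped Newton iterations; the SVM solves the
#' soft-margin RBF dual via [e1071::svm()] and calibrates decision values to
#' probabilities with a Platt logistic map fitted on seeded 3-fold
#' out-of-fold decision values. lncRNA is the positive class throughout.
#'
#' @param features Tibble from [extract_features()] (leading `transcript_id`
#'   column, numeric feature columns).
#' @param labels Vector over `{"lncRNA", "mRNA"}` (or 1/0), one per row.
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling the calibration folds.
#' @param hexamer_table Optional [build_hexamer_table()] result to bundle with
#'   the model so it can be re-applied to raw sequences.
#' @return An `lnc_model` object.
#' @export
train_model <- function(features, labels, spec = model_spec(), seed = 1L,
                        hexamer_table = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- feature_matrix(features)
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) stop("labels and features differ in length", call. = FALSE)
  if (length(unique(y)) < 2L) stop("training needs both classes", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)

  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 0
  Z <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sd[keep])

  if (spec$kind == "logistic") {
    fit <- fit_logistic_irls(Z, y, lambda = spec$lambda)
    params <- fit
  } else {
    gamma <- spec$gamma %||% (1 / ncol(Z))
    yf <- factor(y, levels = c(0, 1))
    svm_fit <- e1071::svm(x = Z, y = yf, type = "C-classification",
                          kernel = "radial", cost = spec$cost, gamma = gamma,
                          scale = FALSE)
    # out-of-fold decision values for Platt calibration
    folds <- stratified_folds(y, k = 3L, seed = seed)
    dv_oof <- numeric(length(y))
    for (f in seq_len(3L)) {
      tr <- folds != f
      m <- e1071::svm(x = Z[tr, , drop = FALSE], y = yf[tr],
                      type = "C-classification", kernel = "radial",
                      cost = spec$cost, gamma = gamma, scale = FALSE)
      pr <- predict(m, Z[!tr, , drop = FALSE], decision.values = TRUE)
      dv_oof[!tr] <- svm_decision_values(pr)
    }
    platt <- fit_logistic_irls(matrix(dv_oof, ncol = 1), y, lambda = 1e-8)
    svm_fit$call <- NULL  # drop call/env for byte-stable serialization
    params <- list(svm = svm_fit, gamma = gamma,
                   platt_intercept = platt$intercept,
                   platt_slope = platt$weights[[1]],
                   oof_decision_values = dv_oof)
  }

  model <- structure(
    list(spec = spec,
         feature_names = colnames(X)[keep],
         dropped_features = colnames(X)[!keep],
         center = mu[keep], scale = sd[keep],
         params = params,
         hexamer_table = hexamer_table,
         threshold = 0.5,
         n_train = length(y),
         format_version = "plantlnc-model-1"),
    class = "lnc_model")

  if (spec$threshold_policy == "youden_cv") {
    folds <- stratified_folds(y, k = 3L, seed = seed)
    sc <- numeric(length(y))
    for (f in seq_len(3L)) {
      tr <- folds != f
      sub <- train_model(features[tr, , drop = FALSE], y[tr],
                         spec = model_spec(spec$kind, spec$schema, spec$lambda,
                                           spec$cost, spec$gamma, "fixed_0.5"),
                         seed = seed + f)
      sc[!tr] <- predict_score(features[!tr, , drop = FALSE], sub)$score
    }
    model$threshold <- youden_threshold(sc, y)
  }
  model
}

# e1071 labels its decision values by class pair; orient so that larger
# decision value means more lncRNA-like is NOT assumed -- the Platt map
# learns the sign. Here we only strip the matrix wrapper.
svm_decision_values <- function(pred) {
  drop(attr(pred, "decision.values"))
}

youden_threshold <- function(scores, y) {
  roc <- roc_curve(scores, ifelse(y == 1, "lncRNA", "mRNA"))
  pts <- roc$points[is.finite(roc$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0L) return(0.5)
  pts$threshold[[which.max(pts$tpr - pts$fpr)]]
}

feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "transcript_id" %in% names(features))
  as.matrix(features[setdiff(names(features), "transcript_id")])
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("lncRNA", "mRNA")))
  as.integer(labels == "lncRNA")
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Predict lncRNA probability scores
#'
#' @param features Feature tibble matching the model's schema.
#' @param model An [train_model()] result.
#' @return Tibble `transcript_id`, `score` with `score` in `[0, 1]`, the
#'   probability that the transcript is a lncRNA (positive class).
#' @export
predict_score <- function(features, model) {
  stopifnot(inherits(model, "lnc_model"))
  X <- feature_matrix(features)
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing) > 0L) {
    stop("feature schema mismatch; missing: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  }
  Z <- scale(X[, model$feature_names, drop = FALSE],
             center = model$center, scale = model$scale)
  score <- if (model$spec$kind == "logistic") {
    plogis(model$params$intercept + drop(Z %*% model$params$weights))
  } else {
    pr <- predict(model$params$svm, Z, decision.values = TRUE)
    dv <- svm_decision_values(pr)
    plogis(model$params$platt_intercept + model$params$platt_slope * dv)
  }
  tibble(transcript_id = features$transcript_id, score = unname(score))
}

#' Classify transcripts with a trained model
#'
#' A transcript is called `lncRNA` iff its score is greater than or equal to
#' the model's decision threshold (boundary scores are lncRNA).
#'
#' @inheritParams predict_score
#' @return Tibble `transcript_id`, `score`, `label`.
#' @export
classify <- function(features, model) {
  sc <- predict_score(features, model)
  sc$label <- ifelse(sc$score >= model$threshold, "lncRNA", "mRNA")
  sc
}

#' Two-model ensemble classification
#'
#' The stringent intersection rule: a transcript is called lncRNA only when
#' BOTH member models call it lncRNA; any disagreement resolves to mRNA. The
#' ensemble positive set is therefore exactly the intersection of the member
#' positive sets, which can only reduce false positives.
#'
#' @param features_a,features_b Feature tibbles for the same transcripts under
#'   each model's schema (matched by `transcript_id`).
#' @param model_a,model_b The two trained member models.
#' @return Tibble `transcript_id`, `score_a`, `score_b`, `label`.
#' @export
ensemble_classify <- function(features_a, features_b, model_a, model_b) {
  a <- classify(features_a, model_a)
  b <- classify(features_b, model_b)
  if (!setequal(a$transcript_id, b$transcript_id)) {
    stop("the two feature sets must cover the same transcripts", call. = FALSE)
  }
  b <- b[match(a$transcript_id, b$transcript_id), , drop = FALSE]
  tibble(transcript_id = a$transcript_id,
         score_a = a$score, score_b = b$score,
         label = ifelse(a$label == "lncRNA" & b$label == "lncRNA",
                        "lncRNA", "mRNA"))
}

#' Train a classifier directly from positive/negative sequence sets
#'
#' Convenience wrapper: builds the hexamer table from the training sequences,
#' extracts the schema's features, and fits the model, bundling the table so
#' the model can later be applied to raw sequences with [classify_sequences()].
#'
#' @param pos Tibble of lncRNA sequences (positive set).
#' @param neg Tibble of mRNA sequences (negative set).
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @param pseudocount Hexamer-table pseudocount.
#' @return An `lnc_model`.
#' @export
train_coding_model <- function(pos, neg, spec = model_spec(), seed = 1L,
                               pseudocount = 1) {
  tab <- build_hexamer_table(coding = neg, noncoding = pos,
                             pseudocount = pseudocount)
  seqs <- dplyr::bind_rows(pos, neg)
  feats <- extract_features(seqs, spec$schema, hexamer_table = tab)
  labels <- c(rep("lncRNA", nrow(pos)), rep("mRNA", nrow(neg)))
  train_model(feats, labels, spec = spec, seed = seed, hexamer_table = tab)
}

#' Apply a trained model (with bundled hexamer table) to raw sequences
#'
#' @param seqs Sequence tibble.
#' @param model An `lnc_model` trained with [train_coding_model()].
#' @return As [classify()].
#' @export
classify_sequences <- function(seqs, model) {
  feats <- extract_features(seqs, model$spec$schema,
                            hexamer_table = model$hexamer_table)
  classify(feats, model)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Folds are stratified by class with a seeded shuffle. Within each fold the
#' hexamer table and the feature standardization are rebuilt from the
#' training partition only, so no information leaks from held-out sequences.
#' Returns per-fold metrics and the pooled confusion over all folds.
#'
#' @param pos,neg Sequence tibbles (lncRNA positives, mRNA negatives).
#' @param spec A [model_spec()].
#' @param k Number of folds (`>= 2`, at most the size of the smaller class).
#' @param seed Integer seed for fold assignment and member training.
#' @return An `lnc_cv` object: list with `folds` (per-fold metric tibble),
#'   `pooled` (one-row pooled metric tibble), and `scores` (per-transcript
#'   out-of-fold scores with truth labels).
#' @export
cross_validate <- function(pos, neg, spec = model_spec(), k = 10L, seed = 1L) {
  validate_sequences(pos)
  validate_sequences(neg)
  stopifnot(k >= 2L)
  if (min(nrow(pos), nrow(neg)) < k) {
    stop("k exceeds the size of the smaller class", call. = FALSE)
  }
  seqs <- dplyr::bind_rows(pos, neg)
  truth <- c(rep("lncRNA", nrow(pos)), rep("mRNA", nrow(neg)))
  y <- as_binary_labels(truth)
  folds <- stratified_folds(y, k = k, seed = seed)

  fold_rows <- list()
  score_rows <- list()
  for (f in seq_len(k)) {
    tr <- folds != f
    model <- train_coding_model(pos = seqs[tr & y == 1L, , drop = FALSE],
                                neg = seqs[tr & y == 0L, , drop = FALSE],
                                spec = spec, seed = seed + f)
    calls <- classify_sequences(seqs[!tr, , drop = FALSE], model)
    cc <- confusion(truth[!tr], calls$label)
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f), cc, metrics(cc))
    score_rows[[f]] <- tibble(transcript_id = calls$transcript_id, fold = f,
                              score = calls$score, truth = truth[!tr],
                              label = calls$label)
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  scores_tbl <- dplyr::bind_rows(score_rows)
  pooled_cc <- tibble(TP = sum(folds_tbl$TP), TN = sum(folds_tbl$TN),
                      FP = sum(folds_tbl$FP), FN = sum(folds_tbl$FN))
  pooled <- dplyr::bind_cols(pooled_cc, metrics(pooled_cc))
  pooled$auc <- roc_curve(scores_tbl$score, scores_tbl$truth)$auc
  structure(list(folds = folds_tbl, pooled = pooled, scores = scores_tbl,
                 k = k, seed = seed, spec = spec),
            class = "lnc_cv")
}

#' Serialize / restore a trained model
#'
#' Single-file archive containing the spec, standardization, parameters,
#' bundled hexamer table, decision threshold and a format-version string.
#'
#' @param model An `lnc_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "lnc_model"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "lnc_model") ||
      !identical(model$format_version, "plantlnc-model-1")) {
    stop("not a plantlnc model file", call. = FALSE)
  }
  model
}

#' @export
print.lnc_model <- function(x, ...) {
  cat("<lnc_model> ", x$spec$kind, " / schema '", x$spec$schema, "'\n",
      "  features: ", length(x$feature_names),
      if (length(x$dropped_features)) paste0(" (dropped ",
                                             length(x$dropped_features), " constant)"),
      "\n  threshold: ", x$threshold,
      "  trained on n = ", x$n_train, "\n", sep = "")
  invisible(x)
}

#' @export
print.lnc_cv <- function(x, ...) {
  cat("<lnc_cv> ", x$k, "-fold cross-validation (", x$spec$kind,
      ", schema '", x$spec$schema, "')\n", sep = "")
  print(x$pooled)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
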