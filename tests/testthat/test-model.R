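toy_features <- function(x) {
  tibble::tibble(transcript_id = paste0("s", seq_along(x)), f1 = x)
}

test_that("separable one-dimensional data is fit perfectly at threshold 0.5", {
  withr::with_seed(1, {
    x <- c(rnorm(50, 1, 0.1), rnorm(50, -1, 0.1))
    labels <- c(rep("lncRNA", 50), rep("mRNA", 50))
    m <- train_model(toy_features(x), labels, model_spec("logistic", "cpat"))
    calls <- classify(toy_features(x), m)
    expect_equal(mean(calls$label == labels), 1)
    expect_equal(m$threshold, 0.5)
  })
})

test_that("label swap negates the logistic weights", {
  withr::with_seed(2, {
    x <- c(rnorm(40, 0.5), rnorm(40, -0.5))  # overlapping classes
    labels <- c(rep("lncRNA", 40), rep("mRNA", 40))
    flipped <- ifelse(labels == "lncRNA", "mRNA", "lncRNA")
    spec <- model_spec("logistic", "cpat", lambda = 0.1)
    m1 <- train_model(toy_features(x), labels, spec)
    m2 <- train_model(toy_features(x), flipped, spec)
    expect_equal(m1$params$weights, -m2$params$weights, tolerance = 1e-6)
    expect_equal(m1$params$intercept, -m2$params$intercept, tolerance = 1e-6)
  })
})

test_that("penalised logistic loss matches a BFGS oracle on a small instance", {
  withr::with_seed(3, {
    n <- 20
    Z <- matrix(rnorm(n * 2), n, 2)
    y <- rbinom(n, 1, plogis(Z[, 1] - 0.5 * Z[, 2]))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    lambda <- 0.1
    fit <- plantlnc:::fit_logistic_irls(Z, y, lambda = lambda)
    nll <- function(b) {
      eta <- b[1] + Z %*% b[-1]
      -sum(y * eta - log1p(exp(eta))) + 0.5 * lambda * sum(b[-1]^2)
    }
    grad <- function(b) {
      eta <- drop(b[1] + Z %*% b[-1])
      mu <- plogis(eta)
      -c(sum(y - mu), drop(crossprod(Z, y - mu))) + c(0, lambda * b[-1])
    }
    oracle <- stats::optim(rep(0, 3), nll, grad, method = "BFGS",
                           control = list(maxit = 1000, reltol = 1e-14))
    expect_equal(nll(c(fit$intercept, fit$weights)), oracle$value,
                 tolerance = 1e-6)
  })
})

test_that("predicted scores equal the direct sigmoid formula", {
  withr::with_seed(4, {
    feats <- tibble::tibble(transcript_id = paste0("s", 1:100),
                            f1 = rnorm(100), f2 = rnorm(100))
    labels <- ifelse(feats$f1 + 0.3 * rnorm(100) > 0, "lncRNA", "mRNA")
    if (length(unique(labels)) < 2) labels[1:2] <- c("lncRNA", "mRNA")
    m <- train_model(feats, labels, model_spec("logistic", "cpat"))
    new <- tibble::tibble(transcript_id = paste0("n", 1:100),
                          f1 = rnorm(100), f2 = rnorm(100))
    got <- predict_score(new, m)$score
    Z <- scale(as.matrix(new[c("f1", "f2")])[, m$feature_names, drop = FALSE],
               m$center, m$scale)
    want <- plogis(m$params$intercept + drop(Z %*% m$params$weights))
    expect_equal(got, unname(want), tolerance = 1e-12)
    # a feature-mean input scores sigmoid(intercept)
    mid <- tibble::tibble(transcript_id = "mid", f1 = m$center[["f1"]],
                          f2 = m$center[["f2"]])
    expect_equal(predict_score(mid, m)$score, plogis(m$params$intercept),
                 tolerance = 1e-12)
  })
})

test_that("logistic scores are monotone in a positive-weight feature", {
  withr::with_seed(5, {
    x <- c(rnorm(30, 1), rnorm(30, -1))
    labels <- c(rep("lncRNA", 30), rep("mRNA", 30))
    m <- train_model(toy_features(x), labels,
                     model_spec("logistic", "cpat", lambda = 0.05))
    expect_gt(m$params$weights[["f1"]], 0)
    grid <- toy_features(seq(-3, 3, length.out = 50))
    sc <- predict_score(grid, m)$score
    expect_true(all(diff(sc) >= 0))
  })
})

test_that("classification uses the documented boundary convention", {
  withr::with_seed(6, {
    x <- c(rnorm(20, 1), rnorm(20, -1))
    labels <- c(rep("lncRNA", 20), rep("mRNA", 20))
    m <- train_model(toy_features(x), labels, model_spec("logistic", "cpat"))
    sc <- predict_score(toy_features(x), m)
    cls <- classify(toy_features(x), m)
    expect_equal(cls$label, ifelse(sc$score >= m$threshold, "lncRNA", "mRNA"))
  })
})

test_that("SVM training works, calibrated scores are monotone in decision values", {
  withr::with_seed(7, {
    feats <- tibble::tibble(transcript_id = paste0("s", 1:120),
                            f1 = c(rnorm(60, 1), rnorm(60, -1)),
                            f2 = rnorm(120))
    labels <- c(rep("lncRNA", 60), rep("mRNA", 60))
    m <- train_model(feats, labels, model_spec("svm_rbf", "plek"), seed = 7)
    sc <- predict_score(feats, m)$score
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gte(mean((sc >= 0.5) == (labels == "lncRNA")), 0.9)
    # Platt map is a monotone transform of the decision value
    Z <- scale(as.matrix(feats[c("f1", "f2")]), m$center, m$scale)
    dv <- plantlnc:::svm_decision_values(
      predict(m$params$svm, Z, decision.values = TRUE))
    expect_equal(order(sc), order(m$params$platt_slope * dv),
                 ignore_attr = TRUE)
  })
})

test_that("training is deterministic given data, spec and seed", {
  withr::with_seed(8, {
    feats <- tibble::tibble(transcript_id = paste0("s", 1:60),
                            f1 = c(rnorm(30, 1), rnorm(30, -1)),
                            f2 = rnorm(60))
  })
  labels <- c(rep("lncRNA", 30), rep("mRNA", 30))
  for (kind in c("logistic", "svm_rbf")) {
    m1 <- train_model(feats, labels, model_spec(kind, "cpat"), seed = 5)
    m2 <- train_model(feats, labels, model_spec(kind, "cpat"), seed = 5)
    expect_identical(m1, m2)
  }
})

test_that("degenerate training inputs are rejected; constants are dropped", {
  feats <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                          f1 = c(1, 2, -1, -2), f2 = c(3, 3, 3, 3))
  expect_error(train_model(feats, rep("lncRNA", 4), model_spec()),
               "both classes")
  expect_error(train_model(dplyr::mutate(feats, f1 = c(1, NaN, 0, 1)),
                           c("lncRNA", "lncRNA", "mRNA", "mRNA"), model_spec()),
               "non-finite")
  m <- train_model(feats, c("lncRNA", "lncRNA", "mRNA", "mRNA"), model_spec())
  expect_equal(m$dropped_features, "f2")
  expect_equal(m$feature_names, "f1")
})

test_that("models survive serialization round trips", {
  withr::with_seed(9, {
    x <- c(rnorm(20, 1), rnorm(20, -1))
    m <- train_model(toy_features(x),
                     c(rep("lncRNA", 20), rep("mRNA", 20)), model_spec())
    path <- withr::local_tempfile(fileext = ".bin")
    write_model(m, path)
    expect_identical(read_model(path), m)
  })
})
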