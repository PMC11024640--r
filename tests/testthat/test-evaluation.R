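test_that("confusion counts equal a direct tally", {
  withr::with_seed(1, {
    truth <- sample(c("lncRNA", "mRNA"), 1000, replace = TRUE)
    pred <- sample(c("lncRNA", "mRNA"), 1000, replace = TRUE)
    cc <- confusion(truth, pred)
    expect_equal(cc$TP, sum(truth == "lncRNA" & pred == "lncRNA"))
    expect_equal(cc$TN, sum(truth == "mRNA" & pred == "mRNA"))
    expect_equal(cc$FP, sum(truth == "mRNA" & pred == "lncRNA"))
    expect_equal(cc$FN, sum(truth == "lncRNA" & pred == "mRNA"))
    expect_equal(cc$TP + cc$FN, sum(truth == "lncRNA"))
  })
  perfect <- confusion(c("lncRNA", "mRNA"), c("lncRNA", "mRNA"))
  expect_equal(perfect$FP + perfect$FN, 0L)
  all_pos <- confusion(c("lncRNA", "mRNA", "mRNA"), rep("lncRNA", 3))
  expect_equal(all_pos$TN, 0L)
  expect_equal(all_pos$FP, 2L)
  expect_error(confusion("lncRNA", c("lncRNA", "mRNA")), "length")
})

test_that("the five metrics match the worked example and the formula oracle", {
  ex <- metrics(tibble::tibble(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(ex$sensitivity, 0.9)
  expect_equal(ex$specificity, 0.8)
  expect_equal(ex$accuracy, 0.85)
  expect_equal(ex$precision, 9 / 11)
  expect_equal(ex$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
  withr::with_seed(2, {
    for (i in 1:200) {
      cnt <- as.list(sample(0:50, 4, replace = TRUE))
      names(cnt) <- c("TP", "TN", "FP", "FN")
      if (sum(unlist(cnt)) == 0) cnt$TP <- 1L
      got <- metrics(tibble::as_tibble(cnt))
      want <- oracle_metrics(cnt$TP, cnt$TN, cnt$FP, cnt$FN)
      expect_equal(unlist(got), want, tolerance = 1e-15)
    }
  })
})

test_that("zero-denominator metrics are undefined, not zero", {
  m <- metrics(tibble::tibble(TP = 0, FP = 0, TN = 5, FN = 3))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_equal(m$sensitivity, 0)
  expect_error(metrics(tibble::tibble(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("ROC endpoints, degenerate ties and perfect separation behave", {
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                   c("lncRNA", "lncRNA", "mRNA", "mRNA"))
  expect_equal(sep$auc, 1)
  tie <- roc_curve(rep(0.5, 6), c(rep("lncRNA", 3), rep("mRNA", 3)))
  expect_equal(tie$auc, 0.5)
  expect_equal(tie$points$fpr, c(0, 1))
  expect_equal(tie$points$tpr, c(0, 1))
  withr::with_seed(3, {
    sc <- rnorm(50)
    truth <- sample(c("lncRNA", "mRNA"), 50, replace = TRUE, prob = c(.5, .5))
    if (length(unique(truth)) < 2) truth[1:2] <- c("lncRNA", "mRNA")
    r <- roc_curve(sc, truth)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(utils::tail(r$points$fpr, 1), 1)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  })
  expect_error(roc_curve(c(1, 2), c("lncRNA", "lncRNA")), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney estimator", {
  withr::with_seed(4, {
    for (i in 1:25) {
      n <- sample(10:200, 1)
      truth <- c(rep("lncRNA", ceiling(n / 3)), rep("mRNA", n))
      sc <- round(runif(length(truth)), sample(1:3, 1))  # force ties
      r <- roc_curve(sc, truth)
      expect_equal(r$auc, oracle_auc_pairwise(sc, truth), tolerance = 1e-12)
      # score reversal maps auc to 1 - auc
      expect_equal(roc_curve(-sc, truth)$auc, 1 - r$auc, tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    truth <- c(rep("lncRNA", 70), rep("mRNA", 90))
    sc <- c(rnorm(70, 1), rnorm(90))
    ours <- roc_curve(sc, truth)$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = sc, levels = c("mRNA", "lncRNA"),
      direction = "<")))
    expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
  })
})

test_that("evaluate_calls joins calls to truth and reports AUC", {
  calls <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                          score = c(0.9, 0.6, 0.4, 0.1),
                          label = c("lncRNA", "lncRNA", "mRNA", "mRNA"))
  truth <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                          label = c("lncRNA", "mRNA", "mRNA", "lncRNA"))
  out <- evaluate_calls(calls, truth)
  expect_equal(out$TP, 1L)
  expect_equal(out$FP, 1L)
  expect_equal(out$accuracy, 0.5)
  expect_true("auc" %in% names(out))
})
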