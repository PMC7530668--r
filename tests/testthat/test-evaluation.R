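test_that("thresholding is >= 0.5 with ties positive", {
  expect_identical(binarize(c(0.7, 0.49, 0.5, 0, 1)), c(1L, 0L, 1L, 0L, 1L))
  expect_error(binarize(1.2), "0, 1")
  expect_error(binarize(-0.1), "0, 1")
})

test_that("rate-form counts satisfy TP + FN = 1 and TN + FP = 1", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:40, 1)
    pred <- rbinom(n, 1, 0.5); truth <- rbinom(n, 1, 0.5)
    ct <- binary_counts(pred, truth)
    expect_identical(ct$tp + ct$fn, sum(truth == 1))
    expect_identical(ct$tn + ct$fp, sum(truth == 0))
    if (!is.na(ct$TP)) expect_equal(ct$TP + ct$FN, 1)
    if (!is.na(ct$TN)) expect_equal(ct$TN + ct$FP, 1)
  }
})

test_that("metric formulas match hand arithmetic and flag undefined ratios", {
  m <- compute_metrics(list(tp = 40, fn = 10, tn = 45, fp = 5))
  expect_equal(m$TPR, 0.8); expect_equal(m$TNR, 0.9); expect_equal(m$ACC, 0.85)
  expect_equal(compute_metrics(list(tp = 8, fp = 2, fn = 2, tn = 0))$F1, 0.8)
  perfect <- compute_metrics(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(perfect$ACC, 1); expect_equal(perfect$F1, 1)
  # no negatives at all: TNR, and only TNR-family, is undefined
  none_neg <- compute_metrics(list(tp = 5, fn = 1, tn = 0, fp = 0))
  expect_true(is.na(none_neg$TNR))
  expect_false(is.na(none_neg$TPR))
  expect_error(compute_metrics(list(tp = -1, tn = 0, fp = 0, fn = 0)),
               "non-negative")
})

test_that("metric set equals the brute-force counting oracle", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    pred <- rbinom(n, 1, runif(1)); truth <- rbinom(n, 1, runif(1))
    got <- compute_metrics(binary_counts(pred, truth))
    want <- oracle_metrics(pred, truth)
    expect_identical(unclass(got)[names(want)], want)
  }
})

test_that("ROC endpoints, degenerate cases and monotone invariance", {
  expect_equal(roc_curve(c(.9, .8, .2, .1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(c(.1, .2, .8, .9), c(1, 1, 0, 0))$auc, 0)
  expect_equal(roc_curve(rep(0.5, 10), rep(0:1, 5))$auc, 0.5)
  r <- roc_curve(runif(20), rep(0:1, 10))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  set.seed(33)
  P <- runif(40); y <- rbinom(40, 1, 0.5)
  expect_equal(roc_curve(P, y)$auc, roc_curve(plogis(5 * P - 2), y)$auc)
  expect_error(roc_curve(runif(5), rep(1, 5)), "positive and")
})

test_that("trapezoidal AUC equals exhaustive pairwise concordance", {
  set.seed(34)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, runif(1)))
    P <- round(runif(n), sample(c(1, 2, 6), 1))   # induce ties sometimes
    expect_equal(roc_curve(P, y)$auc, oracle_auc(P, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(30, 1, 0.4)); P <- runif(32)
    expect_equal(roc_curve(P, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, P, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("confusion matrix keeps only single-annotated single-predicted records", {
  ann <- rbind(encode_labels("AF"), encode_labels(c("AF", "PVC")),
               encode_labels("Normal"), encode_labels("STD"))
  prob <- rbind(c(0, .9, 0, 0, 0, 0, 0, 0, 0),
                c(0, .9, 0, 0, 0, 0, .9, 0, 0),
                c(.2, 0, 0, 0, 0, 0, 0, 0, 0),   # predicted sum 0 -> excluded
                c(0, 0, 0, 0, 0, 0, 0, 0, .8))   # STD predicted as STE
  cm <- confusion_matrix9(prob, ann)
  expect_identical(cm$n_included, 2L)
  expect_identical(cm$n_included + cm$n_excluded, nrow(ann))
  expect_identical(cm$matrix["AF", "AF"], 1L)
  expect_identical(cm$matrix["STD", "STE"], 1L)
  expect_identical(sum(cm$matrix), 2L)
  all_right <- confusion_matrix9(ann * 0.9, ann)
  expect_identical(all_right$n_included, 3L)
  expect_identical(sum(diag(all_right$matrix)), 3L)
  expect_error(confusion_matrix9(prob[, 1:5], ann), "n x 9")
})

test_that("sine fit recovers noiseless coefficients and beats the constant model", {
  x <- c(100, 500, 1000, 1500, 2000)
  y <- 0.9 * sin(1e-5 * x + 0.5)
  f <- fit_sine(x, y)
  expect_lt(max(abs(f$f(x) - y)), 1e-6)
  expect_equal(f$a, 0.9, tolerance = 1e-6)
  expect_equal(f$b, 1e-5, tolerance = 1e-4)
  expect_equal(f$c, 0.5, tolerance = 1e-5)
  for (yy in list(rep(0.8, 5), runif(5, 0.4, 0.6), c(0.5, 0.9, 0.2, 0.7, 0.4))) {
    ff <- fit_sine(x, yy)
    expect_lte(ff$rss, sum((yy - mean(yy))^2) + 1e-9)
  }
})

test_that("evaluate_binary composes counts, metrics and ROC consistently", {
  set.seed(36)
  P <- runif(50); y <- rbinom(50, 1, 0.5)
  ev <- evaluate_binary(P, y)
  expect_identical(ev$counts$tp + ev$counts$fn, sum(y))
  expect_equal(ev$metrics$ACC,
               mean(binarize(P) == y))
  expect_equal(ev$roc$auc, oracle_auc(P, y), tolerance = 1e-12)
})
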