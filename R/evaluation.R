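# Evaluation suite: thresholding at P = 0.5, the fractional count
# metrics (sensitivity, specificity, PPV, NPV, accuracy, F1), empirical
# ROC curves with trapezoidal AUC, the single-disease 9 x 9 confusion
# matrix, and the accuracy-versus-training-size analysis with
# sine-curve fitting.

#' Threshold a probability into a binary decision
#'
#' The default decision threshold is 0.5; a tie at exactly 0.5 counts
#' as positive (documented convention).
#'
#' @param P Probability vector, each value in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 decisions.
#' @export
binarize <- function(P, threshold = 0.5) {
  if (any(!is.finite(P)) || any(P < 0 | P > 1))
    stopf("P must lie in [0, 1]")
  as.integer(P >= threshold)
}

#' Tally binary decision counts
#'
#' @param pred Binary predictions (0/1).
#' @param truth Binary ground truth (0/1).
#' @return `binary_counts`: list with integer `tp`, `tn`, `fp`, `fn`
#'   and the fractional rate forms `TP`, `TN`, `FP`, `FN` (detected /
#'   present episodes etc.; NA when a denominator is zero). The rate
#'   identities TP + FN = 1 and TN + FP = 1 hold whenever defined.
#' @export
binary_counts <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  stopifnot(length(pred) == length(truth),
            all(pred %in% 0:1), all(truth %in% 0:1))
  tp <- sum(pred == 1L & truth == 1L); tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L); fn <- sum(pred == 0L & truth == 1L)
  npos <- tp + fn; nneg <- tn + fp
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 TP = if (npos > 0) tp / npos else NA_real_,
                 FN = if (npos > 0) fn / npos else NA_real_,
                 TN = if (nneg > 0) tn / nneg else NA_real_,
                 FP = if (nneg > 0) fp / nneg else NA_real_),
            class = "binary_counts")
}

#' Classification metrics from binary counts
#'
#' Sensitivity TPR = tp/(tp+fn), specificity TNR = tn/(tn+fp),
#' PPV = tp/(tp+fp), NPV = tn/(tn+fn), ACC = (tp+tn)/n and
#' F1 = 2 tp/(2 tp+fp+fn). A metric whose denominator is zero is
#' reported as NA (undefined), never imputed as 0.
#'
#' @param counts A `binary_counts`, or anything [binary_counts()]-like
#'   with integer fields tp, tn, fp, fn.
#' @return `metric_set`: list with TPR, TNR, PPV, NPV, ACC, F1.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (any(c(tp, tn, fp, fn) < 0)) stopf("counts must be non-negative")
    rat <- function(num, den) if (den > 0) num / den else NA_real_
    structure(list(
      TPR = rat(tp, tp + fn), TNR = rat(tn, tn + fp),
      PPV = rat(tp, tp + fp), NPV = rat(tn, tn + fn),
      ACC = rat(tp + tn, tp + tn + fp + fn),
      F1 = rat(2 * tp, 2 * tp + fp + fn)), class = "metric_set")
  })
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("TPR %.3f  TNR %.3f  PPV %.3f  NPV %.3f  ACC %.3f  F1 %.3f\n",
              x$TPR, x$TNR, x$PPV, x$NPV, x$ACC, x$F1))
  invisible(x)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Thresholds sweep the unique scores plus sentinels, so the curve
#' always starts at (0, 0) and ends at (1, 1). AUC is computed by the
#' trapezoidal rule and is invariant to monotone transforms of the
#' scores.
#'
#' @param P Score (probability) vector.
#' @param truth Binary ground truth (0/1) containing both classes.
#' @return `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(P, truth) {
  truth <- as.integer(truth)
  npos <- sum(truth == 1L); nneg <- sum(truth == 0L)
  if (npos == 0L || nneg == 0L)
    stopf("ROC needs at least one positive and one negative")
  thr <- c(Inf, sort(unique(P), decreasing = TRUE), -Inf)
  ord <- order(P, decreasing = TRUE)
  ps <- P[ord]; ts <- truth[ord]
  # cumulative counts at each unique threshold (score >= thr positive)
  cum_tp <- cumsum(ts); cum_fp <- cumsum(1L - ts)
  last <- !duplicated(ps, fromLast = TRUE)
  tpr <- c(0, cum_tp[last] / npos, 1)
  fpr <- c(0, cum_fp[last] / nneg, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Single-disease 9 x 9 confusion matrix
#'
#' Restricted to records with exactly one annotated AND exactly one
#' predicted (thresholded) class; all other records are excluded, and
#' the inclusion/exclusion counts are reported.
#'
#' @param pred_prob Matrix \[n x 9\] of panel probabilities (columns in
#'   [ECG_CLASSES] order).
#' @param annotations Matrix \[n x 9\] of binary annotations.
#' @param threshold Decision threshold (default 0.5, ties positive).
#' @return `confusion_matrix9`: list with the 9 x 9 integer `matrix`
#'   (rows = true class, columns = predicted class), `n_included`,
#'   `n_excluded`.
#' @export
confusion_matrix9 <- function(pred_prob, annotations, threshold = 0.5) {
  pred_prob <- as.matrix(pred_prob); annotations <- as.matrix(annotations)
  if (ncol(pred_prob) != 9L || ncol(annotations) != 9L ||
      nrow(pred_prob) != nrow(annotations))
    stopf("need n x 9 prediction and annotation matrices of equal height")
  pred_bin <- matrix(as.integer(pred_prob >= threshold), nrow(pred_prob))
  keep <- rowSums(annotations) == 1L & rowSums(pred_bin) == 1L
  m <- matrix(0L, 9L, 9L, dimnames = list(true = ECG_CLASSES,
                                          predicted = ECG_CLASSES))
  for (i in which(keep)) {
    ti <- which(annotations[i, ] == 1L); pi <- which(pred_bin[i, ] == 1L)
    m[ti, pi] <- m[ti, pi] + 1L
  }
  structure(list(matrix = m, n_included = sum(keep),
                 n_excluded = sum(!keep)), class = "confusion_matrix9")
}

#' @export
print.confusion_matrix9 <- function(x, ...) {
  cat(sprintf("<confusion_matrix9> %d records included, %d excluded\n",
              x$n_included, x$n_excluded))
  print(x$matrix)
  invisible(x)
}

#' Fit y = a * sin(b * x + c) by multi-start bounded least squares
#'
#' Starts a Levenberg-Marquardt fit from a grid of frequencies and
#' phases (with a in (0, 1], b > 0) and keeps the lowest residual sum
#' of squares. The frequency is bounded above so that the phase
#' advances at most half a period between adjacent sample points
#' (a Nyquist-style identifiability bound: with sparse x, arbitrarily
#' high-frequency sines interpolate any points exactly and the fit
#' would be pure aliasing). A near-zero-frequency start ensures the
#' fit is never worse than the best constant model.
#'
#' @param x Predictor (e.g. training-set sizes).
#' @param y Response (e.g. accuracies).
#' @param b_max Upper bound for `b`; default `pi / max(diff(sort(x)))`.
#' @return `sine_fit`: list with coefficients `a`, `b`, `c`, the `rss`,
#'   and a `predict`-ready function `f`.
#' @export
fit_sine <- function(x, y, b_max = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (is.null(b_max)) b_max <- pi / max(diff(sort(unique(x))))
  sse <- function(p) sum((y - p[1] * sin(p[2] * x + p[3]))^2)
  best <- NULL
  try_fit <- function(start) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * sin(b * x + c),
                        start = list(a = start[1], b = start[2], c = start[3]),
                        lower = c(a = 1e-9, b = 1e-12, c = -2 * pi),
                        upper = c(a = 1, b = b_max, c = 2 * pi),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return()
    p <- stats::coef(fit)
    r <- sse(p)
    # ties in RSS are broken toward the smallest frequency: several
    # sines can interpolate sparse points equally well, and the
    # smoothest one is the identifiable choice
    tol <- 1e-14 * (1 + sum(y^2))
    if (is.null(best) || r < best$rss - tol ||
        (r < best$rss + tol && p["b"] < best$b))
      best <<- list(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"]),
                    rss = r)
  }
  a0 <- min(1, max(abs(y), 1e-3))
  span <- max(diff(range(x)), 1e-12)
  for (b0 in unique(pmin(b_max, c(10^seq(-7, 0, by = 0.5) * (2 * pi / span),
                                  pi / span, b_max))))
    for (c0 in seq(-1.45, 1.45, by = 0.58))
      try_fit(c(a0, b0, c0))
  # near-constant start: a*sin(c) ~ mean(y) with b -> 0
  mu <- mean(y)
  if (abs(mu) <= 1) try_fit(c(max(abs(mu), 1e-3), 1e-10,
                              asin(max(-1, min(1, mu / max(abs(mu), 1e-3))))))
  const_rss <- sum((y - mu)^2)
  if (is.null(best) || best$rss > const_rss + 1e-9) {
    a <- max(abs(mu), 1e-9)
    best <- list(a = a, b = 1e-12, c = asin(max(-1, min(1, mu / a))),
                 rss = const_rss)
  }
  best$f <- function(xx) best$a * sin(best$b * xx + best$c)
  structure(best, class = "sine_fit")
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf("<sine_fit> y = %.4g * sin(%.4g * x + %.4g), RSS = %.3g\n",
              x$a, x$b, x$c, x$rss))
  invisible(x)
}

#' Accuracy as a function of training-set size
#'
#' Trains a fresh CNN-dig classifier on nested subsets of the training
#' records of increasing size, evaluates accuracy (threshold 0.5) each
#' time on the identical test set, and fits y = a sin(b x + c) to the
#' (size, accuracy) points.
#'
#' @param train_ds Training `ecg_dataset`.
#' @param test_ds Fixed test `ecg_dataset`.
#' @param disease Target condition name.
#' @param sizes Increasing vector of training-subset sizes (each <=
#'   number of training records).
#' @param spec CNN-dig architecture spec (a reduced-width spec keeps
#'   the sweep cheap).
#' @param config A [train_config()].
#' @param seed Integer seed.
#' @param val_frac Fraction of each subset held out as validation.
#' @return `size_accuracy_fit`: list with `points` (data.frame of size,
#'   accuracy) and the [fit_sine()] result `fit`.
#' @export
accuracy_vs_size <- function(train_ds, test_ds, disease = "AF",
                             sizes = c(100L, 500L, 2000L),
                             spec = cnn_dig_spec(base_channels = 8,
                                                 cap_channels = 8),
                             config = train_config(lr = 1e-3, batch_size = 32L,
                                                   max_epochs = 8L,
                                                   patience = 8L),
                             seed = 1L, val_frac = 0.15) {
  if (any(sizes > train_ds$n))
    stopf("requested size exceeds available training records (%d)", train_ds$n)
  di <- match(disease, ECG_CLASSES)
  if (is.na(di)) stopf("unknown disease: %s", disease)
  y_test <- test_ds$labels[di, ]
  order_all <- with_seed(child_seed(seed, 1L), sample(train_ds$n))
  acc <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    idx <- order_all[seq_len(sizes[k])]
    n_val <- max(2L, round(val_frac * length(idx)))
    val_idx <- idx[seq_len(n_val)]; tr_idx <- idx[-seq_len(n_val)]
    sub <- train_ds[tr_idx]; val <- train_ds[val_idx]
    if (length(unique(sub$labels[di, ])) < 2L || length(unique(val$labels[di, ])) < 2L)
      stopf("subset of size %d is single-class; increase sizes", sizes[k])
    tm <- train_model(build_cnn_dig(spec), sub, sub$labels[di, ], val,
                      val$labels[di, ], config,
                      seed = child_seed(seed, 10L + k), disease = disease)
    pred <- binarize(predict(tm, test_ds))
    acc[k] <- mean(pred == y_test)
  }
  points <- data.frame(size = sizes, accuracy = acc)
  structure(list(points = points, fit = fit_sine(sizes, acc)),
            class = "size_accuracy_fit")
}

#' @export
print.size_accuracy_fit <- function(x, ...) {
  print(x$points); print(x$fit)
  invisible(x)
}

#' Per-disease evaluation report
#'
#' Computes counts, the metric set and the ROC curve for one disease's
#' probabilities against binary truth.
#'
#' @param P Probability vector.
#' @param truth Binary truth vector.
#' @param threshold Decision threshold.
#' @return List with `counts`, `metrics`, `roc`.
#' @export
evaluate_binary <- function(P, truth, threshold = 0.5) {
  counts <- binary_counts(binarize(P, threshold), truth)
  list(counts = counts, metrics = compute_metrics(counts),
       roc = roc_curve(P, truth))
}
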