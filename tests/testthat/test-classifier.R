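# Metrics, ROC/AUC, SVM grid search and cross-validation.

test_that("metric formulas reproduce a hand-evaluated confusion matrix", {
  # TP=8 FN=2 TN=9 FP=1
  y <- c(rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 8), rep(0, 2), rep(0, 9), 1)
  rep_ <- eval_report(pred, y)
  expect_equal(rep_$tp, 8); expect_equal(rep_$fn, 2)
  expect_equal(rep_$tn, 9); expect_equal(rep_$fp, 1)
  expect_equal(rep_$sn, 0.800, tolerance = 1e-3)
  expect_equal(rep_$sp, 0.900, tolerance = 1e-3)
  expect_equal(rep_$acc, 0.850, tolerance = 1e-3)
  expect_equal(rep_$precision, 0.8889, tolerance = 1e-4)
  expect_equal(rep_$f1, 0.8421, tolerance = 1e-4)
  expect_equal(rep_$mcc, 0.7035, tolerance = 1e-4)
})

test_that("metrics agree with the confusion oracle on random cases", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    r <- eval_report(pred, y)
    o <- oracle_metrics(r$tp, r$fp, r$tn, r$fn)
    expect_equal(metric_vector(r)[names(o)], o, tolerance = 1e-12)
    expect_gte(r$mcc, -1); expect_lte(r$mcc, 1)
  }
})

test_that("undefined-denominator metrics are zero and flagged", {
  r <- eval_report(pred = c(0, 0, 0, 0), y = c(1, 1, 0, 0))
  expect_equal(r$precision, 0)
  expect_true("precision" %in% r$undefined)
  expect_equal(r$sn, 0)
})

test_that("ROC sweeps thresholds correctly and AUC behaves", {
  y <- c(1, 1, 1, 0, 0, 0)
  # perfect ranking
  p1 <- roc_curve(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), y)
  expect_equal(p1$auc, 1)
  expect_equal(p1$roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(p1$roc[nrow(p1$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(p1$roc$fpr) >= 0) && all(diff(p1$roc$tpr) >= 0))
  # constant score: single threshold, trapezoid gives 0.5
  expect_equal(roc_curve(rep(0.5, 6), y)$auc, 0.5)
  # monotone-transform invariance
  set.seed(11)
  s <- rnorm(40); yy <- rbinom(40, 1, 0.5)
  expect_equal(roc_curve(s, yy)$auc, roc_curve(exp(3 * s) + 2, yy)$auc)
  # agreement with an established ROC implementation
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_curve(s, yy)$auc, auc_ref, tolerance = 1e-12)
})

test_that("MCC and AUC are null for label-independent predictors", {
  set.seed(12)
  y <- rbinom(100, 1, 0.5)
  r <- eval_report(rep(1, 100), y, scores = rep(0, 100))
  expect_equal(r$mcc, 0)
  expect_equal(r$auc, 0.5)
})

test_that("stratified folds are balanced, seeded, and bounded by class size", {
  y <- rep(c(0, 1), c(30, 20))
  f <- stratified_folds(y, 5, seed = 3)
  expect_equal(as.vector(table(f)), rep(10, 5))
  for (k in 1:5) expect_equal(sum(y[f == k]), 4)   # 4 positives per fold
  expect_identical(f, stratified_folds(y, 5, seed = 3))
  expect_error(stratified_folds(y, 25, seed = 1), "smaller class")
  f2 <- stratified_folds(c(0, 0, 1, 1), 2, seed = 1)
  expect_equal(as.vector(table(f2)), c(2, 2))
})

test_that("SVM grid search is an argmax with parsimonious tie-breaks", {
  set.seed(13)
  n <- 60
  y <- rep(0:1, each = n / 2)
  X <- cbind(x1 = y * 3 + rnorm(n, sd = 0.3), x2 = rnorm(n))
  cfg <- svm_config(C_grid = c(0.1, 1, 10), gamma_grid = c(0.01, 0.1, 1),
                    seed = 5)
  fit <- train_svm(X, y, cfg, folds = 5)
  expect_equal(fit$cv_acc, max(fit$grid$acc))
  # ties resolved toward smaller C then smaller gamma
  top <- fit$grid[fit$grid$acc == fit$cv_acc, ]
  expect_equal(fit$C, min(top$C))
  expect_equal(fit$gamma, min(top$gamma[top$C == min(top$C)]))
  # single-point grid is chosen trivially
  cfg1 <- svm_config(C_grid = 2, gamma_grid = 0.05, seed = 5)
  fit1 <- train_svm(X, y, cfg1, folds = 5)
  expect_equal(fit1$C, 2); expect_equal(fit1$gamma, 0.05)
  # linearly separable toy data: training accuracy 1 with linear kernel
  Xs <- cbind(x1 = c(rep(-2, 10), rep(2, 10)) + rnorm(20, sd = 0.1),
              x2 = rnorm(20))
  ys <- rep(0:1, each = 10)
  fl <- train_svm(Xs, ys, svm_config(kernel = "linear", C_grid = 1,
                                     seed = 1), folds = 5)
  expect_equal(evaluate_svm(fl, Xs, ys)$acc, 1)
})

test_that("the SVM recovers a planted motif from position-aware features", {
  ws <- simulate_windows(200, 200, motif_prob = 1, seed = 20)
  y <- window_labels(ws)
  # position-resolved ENAC blocks covering the motif carry most of the
  # recoverable signal (the ideal positional rule reaches ~0.97 here)
  Xe <- encode_windows(ws, views = "enac")
  keep <- grepl("w1[89]|w2[0123]", colnames(Xe))
  fit <- train_svm(Xe[, keep], y,
                   svm_config(C_grid = c(1, 10, 100),
                              gamma_grid = c(0.01, 0.1, 1), seed = 2),
                   folds = 5)
  expect_gt(fit$cv_acc, 0.9)
  # position-agnostic Kmer counts see the motif only weakly (background
  # occurrences cap the ideal count rule near 0.77) but still beat chance
  Xk <- encode_windows(ws, views = "kmer", kmer_k = 3)
  fitk <- train_svm(Xk, y, fast_svm(seed = 2), folds = 5)
  expect_gt(fitk$cv_acc, 0.6)
  expect_lt(fitk$cv_acc, 0.9)
})

test_that("cross-validation is seeded and consistent with hold-out accuracy", {
  ws <- simulate_windows(120, 120, motif_prob = 1, seed = 21)
  X <- encode_windows(ws, views = "kmer", kmer_k = 3)
  y <- window_labels(ws)
  cfg <- svm_config(C = 10, gamma = 0.1, seed = 7)
  cv <- cross_validate(X, y, cfg, folds = 5)
  cv2 <- cross_validate(X, y, cfg, folds = 5)
  expect_identical(cv$fold, cv2$fold)
  expect_equal(cv$mean, cv2$mean)
  expect_equal(length(cv$per_fold), 5)
  # pooled confusion counts add up to n
  expect_equal(with(cv$pooled, tp + fp + tn + fn), 240)
  # fold-mean accuracy within sampling error of a fresh hold-out estimate
  hold <- simulate_windows(100, 100, motif_prob = 1, seed = 22)
  Xh <- encode_windows(hold, views = "kmer", kmer_k = 3)
  m <- train_svm(X, y, svm_config(C_grid = 10, gamma_grid = 0.1, seed = 7),
                 folds = 5)
  acc_hold <- evaluate_svm(m, Xh, window_labels(hold))$acc
  expect_lt(abs(cv$mean[["acc"]] - acc_hold), 0.1)
})
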