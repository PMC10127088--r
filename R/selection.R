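# Two-step feature optimization: importance ranking (ANOVA F, F-score, or
# gradient-boosted-tree gain) followed by accuracy-based incremental feature
# selection (IFS) under stratified cross-validation.

new_ranking <- function(method, names, scores) {
  # stable sort: descending score, ties by original column order
  ord <- order(-scores, seq_along(scores))
  structure(list(method = method, names = names[ord],
                 scores = unname(scores[ord])),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<feature_ranking> method=%s, %d features; top %d:\n",
              x$method, length(x$names), min(n, length(x$names))))
  print(utils::head(data.frame(feature = x$names, score = x$scores), n))
  invisible(x)
}

check_xy <- function(X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  if (min(table(y)) < 2) stop("at least 2 samples per class required",
                              call. = FALSE)
  y
}

#' Rank features by one-way ANOVA F statistic
#'
#' Per feature, the two-group one-way ANOVA F statistic (between-class mean
#' square over within-class mean square). Features that are constant overall
#' score 0 and rank last.
#'
#' @param X feature matrix (samples x features, named columns).
#' @param y 0/1 labels.
#' @return A `feature_ranking` (descending scores).
#' @export
rank_anova <- function(X, y) {
  y <- check_xy(X, y)
  n <- length(y)
  g1 <- y == 1; g0 <- !g1
  n1 <- sum(g1); n0 <- sum(g0)
  m <- colMeans(X); m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[g0, , drop = FALSE])
  ss_between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ss_within <- colSums((X[g1, , drop = FALSE] -
                          matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
               colSums((X[g0, , drop = FALSE] -
                          matrix(m0, n0, ncol(X), byrow = TRUE))^2)
  f <- (ss_between / 1) / (ss_within / (n - 2))
  f[ss_between == 0 & ss_within == 0] <- 0     # constant feature
  f[!is.finite(f)] <- 0
  new_ranking("anova", colnames(X), f)
}

#' Rank features by the feature-selection F-score
#'
#' The standard two-class F-score:
#' `((m_pos - m)^2 + (m_neg - m)^2) / (var_pos + var_neg)` with sample
#' variances; a zero denominator with equal means scores 0.
#'
#' @inheritParams rank_anova
#' @return A `feature_ranking`.
#' @export
rank_fscore <- function(X, y) {
  y <- check_xy(X, y)
  g1 <- y == 1; g0 <- !g1
  m <- colMeans(X)
  m1 <- colMeans(X[g1, , drop = FALSE]); m0 <- colMeans(X[g0, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[g0, , drop = FALSE], 2, stats::var)
  num <- (m1 - m)^2 + (m0 - m)^2
  den <- v1 + v0
  s <- ifelse(den == 0, ifelse(num == 0, 0, Inf), num / den)
  # a perfectly separating constant-within-class feature outranks everything
  s[is.infinite(s)] <- max(s[is.finite(s)], 0) + 1 + num[is.infinite(s)]
  new_ranking("fscore", colnames(X), s)
}

#' Rank features by gradient-boosted-tree gain importance
#'
#' Fits a seeded gradient-boosted decision-tree ensemble (xgboost backend)
#' and ranks features by total split gain; features never used by the
#' ensemble score 0 and keep their original column order among themselves.
#'
#' @inheritParams rank_anova
#' @param backend `"gbdt_xgboost"` (or alias `"xgboost"`). A LightGBM
#'   backend is recognized but not available in R; requesting it raises a
#'   capability error pointing to the other ranking methods.
#' @param seed integer seed.
#' @param nrounds boosting rounds (default 100).
#' @return A `feature_ranking`.
#' @export
rank_tree_importance <- function(X, y,
                                 backend = c("gbdt_xgboost", "xgboost",
                                             "gbdt_lightgbm", "lightgbm"),
                                 seed = 1, nrounds = 100) {
  backend <- match.arg(backend)
  if (backend %in% c("gbdt_lightgbm", "lightgbm"))
    stop("LightGBM backend is not available; use backend='gbdt_xgboost' ",
         "or the anova/fscore rankings", call. = FALSE)
  y <- check_xy(X, y)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 4, eta = 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  scores <- stats::setNames(numeric(ncol(X)), colnames(X))
  scores[imp$Feature] <- imp$Gain
  new_ranking("gbdt_xgboost", colnames(X), scores)
}

#' Rank features with a named method
#'
#' @inheritParams rank_anova
#' @param method `"anova"`, `"fscore"`, or `"gbdt_xgboost"`
#'   (`"gbdt_lightgbm"` is recognized but unavailable).
#' @param seed seed for tree backends.
#' @return A `feature_ranking`.
#' @export
rank_features <- function(X, y, method = c("gbdt_xgboost", "anova", "fscore",
                                           "gbdt_lightgbm"), seed = 1) {
  method <- match.arg(method)
  switch(method,
         anova = rank_anova(X, y),
         fscore = rank_fscore(X, y),
         rank_tree_importance(X, y, backend = method, seed = seed))
}

#' Accuracy-based incremental feature selection (IFS)
#'
#' Walks down the importance ranking in prefixes of size `step`, `2*step`,
#' ..., training the configured SVM under stratified k-fold CV on each
#' prefix with one fixed seeded fold partition (so prefix accuracies are
#' comparable), and returns the smallest prefix attaining the maximum mean
#' accuracy.
#'
#' @param ranking a `feature_ranking` covering `X`'s columns.
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param cfg an [svm_config()] used (at its fixed C/gamma) inside the scan.
#' @param folds CV folds (default 10).
#' @param step prefix increment (default 1; the full matrix is always
#'   evaluated as the final prefix).
#' @param seed seed for the fold partition.
#' @return A `selection_result`: `ranking`, `prefix_sizes`, `prefix_acc`,
#'   `best_size`, `best_features`.
#' @export
incremental_feature_selection <- function(ranking, X, y, cfg = svm_config(),
                                          folds = 10, step = 1, seed = 1) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!setequal(ranking$names, colnames(X)))
    stop("ranking does not cover the feature matrix columns", call. = FALSE)
  y <- as.integer(y)
  p <- ncol(X)
  sizes <- unique(c(seq(step, p, by = step), p))
  fold <- stratified_folds(y, folds, seed = seed)
  acc <- vapply(sizes, function(sz) {
    Xs <- X[, ranking$names[seq_len(sz)], drop = FALSE]
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_svm_once(Xs[tr, , drop = FALSE], y[tr], cfg, cfg$C, cfg$gamma)
      mean(svm_scores(m, Xs[!tr, , drop = FALSE])$pred == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  best_size <- sizes[which.max(acc)]        # first max = smallest prefix
  structure(list(ranking = ranking, prefix_sizes = sizes, prefix_acc = acc,
                 best_size = best_size,
                 best_features = ranking$names[seq_len(best_size)]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method=%s: best prefix %d/%d features, CV acc %.4f\n",
              x$ranking$method, x$best_size, length(x$ranking$names),
              max(x$prefix_acc)))
  invisible(x)
}

#' @export
plot.selection_result <- function(x, ...) {
  graphics::plot(x$prefix_sizes, x$prefix_acc, type = "b", pch = 16,
                 xlab = "number of top-ranked features",
                 ylab = "CV accuracy", main = "Incremental feature selection", ...)
  graphics::abline(v = x$best_size, lty = 2, col = "red")
  invisible(x)
}

#' Write a selection result as TSV plus a JSON summary
#'
#' @param sel a [incremental_feature_selection()] result.
#' @param path TSV path (rank, feature, score, plus the IFS curve in
#'   `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_selection <- function(sel, path) {
  utils::write.table(
    data.frame(rank = seq_along(sel$ranking$names),
               feature = sel$ranking$names, score = sel$ranking$scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = sel$ranking$method,
                            prefix_sizes = sel$prefix_sizes,
                            prefix_acc = sel$prefix_acc,
                            best_size = sel$best_size,
                            best_features = sel$best_features),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
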