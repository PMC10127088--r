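# SVM classification: configuration, seeded stratified folds, grid search
# by cross-validated accuracy, and fold-wise evaluation. The quadratic
# program itself is solved by libsvm (via e1071); this module owns the
# kernel/C/gamma surface, the grid search, and the seeding.

#' SVM configuration
#'
#' @param kernel one of `"rbf"`, `"linear"`, `"polynomial"`, `"sigmoid"`.
#' @param C regularization (cost) parameter, > 0.
#' @param gamma kernel width: positive number or `"scale"` (1 / (p * var(X)),
#'   resolved at fit time).
#' @param C_grid,gamma_grid candidate lists for grid search. Defaults follow
#'   canonical SVM grid-search practice: C in 2^(-5..15), gamma in 2^(-15..3),
#'   both by powers of 4.
#' @param scale standardize columns inside the fit (default `TRUE`).
#' @param seed seed for the fold partition used during grid search.
#' @return An `svm_config` list.
#' @export
svm_config <- function(kernel = c("rbf", "linear", "polynomial", "sigmoid"),
                       C = 1, gamma = "scale",
                       C_grid = 4^(-2:7) / 8, gamma_grid = 4^(-7:1) / 2,
                       scale = TRUE, seed = 1) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma,
                 C_grid = sort(C_grid), gamma_grid = sort(gamma_grid),
                 scale = scale, seed = as.integer(seed)),
            class = "svm_config")
}

# 1 / (p * var) heuristic, computed on the matrix the kernel actually sees:
# with scale = TRUE e1071 standardizes columns first, so the variance is 1.
resolve_gamma <- function(gamma, X, scaled = TRUE) {
  if (identical(gamma, "scale")) {
    v <- if (scaled) 1 else stats::var(as.vector(X))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(X) * v)
  } else gamma
}

e1071_kernel <- function(kernel) {
  switch(kernel, rbf = "radial", linear = "linear",
         polynomial = "polynomial", sigmoid = "sigmoid")
}

#' Seeded stratified fold assignment
#'
#' @param y 0/1 labels.
#' @param folds number of folds (each class is spread evenly across folds).
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(y, folds, seed = 1) {
  y <- as.integer(y)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (min(table(y)) < folds)
    stop("folds exceeds the size of the smaller class", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

fit_svm_once <- function(X, y, cfg, C, gamma) {
  y_f <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
  e1071::svm(x = X, y = y_f, kernel = e1071_kernel(cfg$kernel),
             cost = C, gamma = resolve_gamma(gamma, X, cfg$scale),
             scale = cfg$scale)
}

# Decision scores oriented so larger = positive class.
svm_scores <- function(model, X) {
  pr <- stats::predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- dv[, 1]
  # column name "a/b": positive value favors class a
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first != "pos") s <- -s
  list(pred = as.integer(pr == "pos"), scores = unname(s))
}

#' Train an SVM with grid search over (C, gamma)
#'
#' Every grid candidate is scored by mean stratified k-fold CV accuracy on
#' one fixed seeded partition; the best `(C, gamma)` (ties: smaller C, then
#' smaller gamma) is refit on all of the data. For kernels without a gamma
#' (linear), only the C grid is searched.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param cfg an [svm_config()].
#' @param folds CV folds for the grid search (default 10).
#' @return An `m5u_svm` list: `model` (e1071 fit), `C`, `gamma`, `cv_acc`
#'   (accuracy of the winning cell), `grid` (all cells), `cfg`.
#' @export
train_svm <- function(X, y, cfg = svm_config(), folds = 10) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("two classes required", call. = FALSE)
  fold <- stratified_folds(y, folds, seed = cfg$seed)
  gamma_grid <- if (cfg$kernel == "linear") NA else cfg$gamma_grid
  grid <- expand.grid(C = cfg$C_grid, gamma = gamma_grid)
  grid$acc <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      m <- fit_svm_once(X[tr, , drop = FALSE], y[tr], cfg,
                        grid$C[i], if (is.na(grid$gamma[i])) "scale" else grid$gamma[i])
      mean(svm_scores(m, X[!tr, , drop = FALSE])$pred == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-grid$acc, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  gamma_best <- if (is.na(best$gamma)) "scale" else best$gamma
  model <- fit_svm_once(X, y, cfg, best$C, gamma_best)
  structure(list(model = model, C = best$C, gamma = gamma_best,
                 cv_acc = best$acc, grid = grid, cfg = cfg,
                 feature_names = colnames(X)),
            class = "m5u_svm")
}

#' @export
print.m5u_svm <- function(x, ...) {
  cat(sprintf("<m5u_svm> kernel=%s, C=%g, gamma=%s, grid CV acc=%.4f\n",
              x$cfg$kernel, x$C,
              if (is.numeric(x$gamma)) format(x$gamma) else x$gamma, x$cv_acc))
  invisible(x)
}

#' @export
predict.m5u_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (!is.null(object$feature_names)) {
    if (is.null(colnames(newdata)) ||
        !identical(colnames(newdata), object$feature_names)) {
      if (!is.null(colnames(newdata)) &&
          all(object$feature_names %in% colnames(newdata))) {
        newdata <- newdata[, object$feature_names, drop = FALSE]
      } else {
        stop("newdata feature names do not match the training features",
             call. = FALSE)
      }
    }
  }
  s <- svm_scores(object$model, newdata)
  if (type == "class") s$pred else s$scores
}

#' Evaluate a trained SVM on labeled data
#'
#' @param fit an [train_svm()] result.
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @return An [eval_report()] at the default decision threshold, with ROC
#'   and AUC from the signed decision values.
#' @export
evaluate_svm <- function(fit, X, y) {
  s <- svm_scores(fit$model, X)
  eval_report(s$pred, as.integer(y), scores = s$scores)
}

#' Stratified k-fold cross-validation of an SVM configuration
#'
#' Fits at the configuration's fixed `(C, gamma)` on each training split and
#' evaluates on the held-out fold. Reports per-fold metrics, their mean, and
#' a pooled report over the concatenated held-out predictions.
#'
#' @param X feature matrix.
#' @param y 0/1 labels.
#' @param cfg an [svm_config()]; its `C`/`gamma` fields are used as-is.
#' @param folds number of folds (default 10).
#' @param seed seed for the fold partition (default: the config seed).
#' @return A `cv_report`: list with `per_fold` (list of [eval_report()]),
#'   `mean` (named metric means across folds), `pooled` ([eval_report()]),
#'   `fold` (assignment vector).
#' @export
cross_validate <- function(X, y, cfg = svm_config(), folds = 10,
                           seed = cfg$seed) {
  y <- as.integer(y)
  fold <- stratified_folds(y, folds, seed = seed)
  pred <- integer(length(y)); scores <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    m <- fit_svm_once(X[tr, , drop = FALSE], y[tr], cfg, cfg$C, cfg$gamma)
    s <- svm_scores(m, X[!tr, , drop = FALSE])
    pred[!tr] <- s$pred; scores[!tr] <- s$scores
    per_fold[[f]] <- eval_report(s$pred, y[!tr], scores = s$scores)
  }
  mean_metrics <- colMeans(do.call(rbind, lapply(per_fold, metric_vector)))
  structure(list(per_fold = per_fold, mean = mean_metrics,
                 pooled = eval_report(pred, y, scores = scores),
                 fold = fold),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 4, ...) {
  cat(sprintf("<cv_report> %d folds\nfold-mean metrics:\n", length(x$per_fold)))
  print(round(x$mean, digits))
  cat("pooled:\n")
  print(x$pooled, digits = digits)
  invisible(x)
}
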