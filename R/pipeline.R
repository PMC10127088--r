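# End-to-end orchestration. The ordering is fixed by the method: the four
# physicochemical views are fused and the two-step selection runs on that
# fused matrix only; the skip-gram embedding features join afterwards
# (they are never filtered by IFS), and the SVM is tuned and evaluated on
# the final multi-view matrix.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end fit, with the method's standard
#' settings as defaults: 41-nt windows, Kmer k = 1..3, ENAC window 5, CKSNAP
#' gaps 0..5, PseDNC lambda 3 / w 0.5, skip-gram k = 3 / context 4 /
#' dimension 100, gradient-boosted-tree ranking + IFS, RBF-kernel SVM with
#' grid search under stratified tenfold CV.
#'
#' @param L window length (odd).
#' @param views physicochemical views to fuse (order fixed internally to
#'   CKSNAP, ENAC, Kmer, PseDNC).
#' @param kmer_k Kmer block sizes.
#' @param enac_window ENAC sliding-window length.
#' @param cksnap_kmax largest CKSNAP gap.
#' @param psednc_lam,psednc_w PseDNC lambda and weight.
#' @param property_table_path optional TSV overriding the bundled property
#'   table.
#' @param embed_k,embed_w,embed_dim,embed_epochs skip-gram hyperparameters.
#' @param selection_method,selection_folds,selection_step two-step selection
#'   settings (see [rank_features()], [incremental_feature_selection()]).
#' @param svm an [svm_config()].
#' @param folds CV folds for evaluation (default 10).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return An `m5u_config` list.
#' @export
m5u_config <- function(L = 41,
                       views = c("cksnap", "enac", "kmer", "psednc"),
                       kmer_k = 1:3, enac_window = 5, cksnap_kmax = 5,
                       psednc_lam = 3, psednc_w = 0.5,
                       property_table_path = NULL,
                       embed_k = 3, embed_w = 4, embed_dim = 100,
                       embed_epochs = 50,
                       selection_method = "gbdt_xgboost",
                       selection_folds = 10, selection_step = 1,
                       svm = svm_config(), folds = 10, seed = 1) {
  structure(list(L = L, views = views, kmer_k = kmer_k,
                 enac_window = enac_window, cksnap_kmax = cksnap_kmax,
                 psednc_lam = psednc_lam, psednc_w = psednc_w,
                 property_table_path = property_table_path,
                 embed_k = embed_k, embed_w = embed_w, embed_dim = embed_dim,
                 embed_epochs = embed_epochs,
                 selection_method = selection_method,
                 selection_folds = selection_folds,
                 selection_step = selection_step,
                 svm = svm, folds = folds, seed = as.integer(seed)),
            class = "m5u_config")
}

config_physchem_args <- function(cfg, table) {
  list(views = cfg$views, kmer_k = cfg$kmer_k, enac_window = cfg$enac_window,
       cksnap_kmax = cfg$cksnap_kmax,
       psednc_cfg = psednc_config(cfg$psednc_lam, cfg$psednc_w),
       property_table = table)
}

#' Fit the m5U site prediction model
#'
#' Runs the full method on a labeled window set: (1) fused physicochemical
#' encoding (CKSNAP + ENAC + Kmer + PseDNC); (2) two-step feature
#' optimization — importance ranking then accuracy-based incremental feature
#' selection — on the fused physicochemical matrix; (3) skip-gram k-mer
#' embedding of the training windows, mean-pooled per window; (4) fusion of
#' the selected physicochemical features with the embedding features;
#' (5) SVM grid search over (C, gamma) and stratified k-fold
#' cross-validation on the multi-view matrix; (6) final refit on all
#' training data.
#'
#' @param train a labeled [window_set()].
#' @param config an [m5u_config()].
#' @return An object of class `m5u_fit` with components `config`,
#'   `property_table`, `ranking`, `selection`, `embedding`, `svm`
#'   (the tuned [train_svm()] fit), `cv` (a `cv_report`), `feature_names`.
#' @seealso [predict.m5u_fit()], [interpret()], [run_pipeline()]
#' @export
m5u_fit <- function(train, config = m5u_config()) {
  stopifnot(inherits(train, "window_set"))
  if (train$L != config$L)
    stop(sprintf("window length %d does not match configured L=%d",
                 train$L, config$L), call. = FALSE)
  y <- window_labels(train)
  table <- load_property_table(config$property_table_path)

  phys_args <- config_physchem_args(config, table)
  X_phys <- do.call(encode_windows, c(list(train), phys_args))

  ranking <- rank_features(X_phys, y, method = config$selection_method,
                           seed = config$seed)
  selection <- incremental_feature_selection(
    ranking, X_phys, y, cfg = config$svm, folds = config$selection_folds,
    step = config$selection_step, seed = config$seed)

  corpus <- build_corpus(train, k = config$embed_k)
  embedding <- train_skipgram(corpus, dim = config$embed_dim,
                              w = config$embed_w,
                              epochs = config$embed_epochs,
                              seed = config$seed)
  X_embed <- embed_windows(train, embedding)

  X <- cbind(X_phys[, selection$best_features, drop = FALSE], X_embed)

  svm_fit <- train_svm(X, y, cfg = config$svm, folds = config$folds)
  cv_cfg <- config$svm
  cv_cfg$C <- svm_fit$C
  cv_cfg$gamma <- svm_fit$gamma
  cv <- cross_validate(X, y, cfg = cv_cfg, folds = config$folds,
                       seed = config$seed)

  structure(list(config = config, property_table = table,
                 ranking = ranking, selection = selection,
                 embedding = embedding, svm = svm_fit, cv = cv,
                 feature_names = colnames(X), train_ids = train$windows$id,
                 X = X, y = y),
            class = "m5u_fit")
}

#' Build the multi-view feature matrix for new windows under a fit
#'
#' @param object an [m5u_fit()] model.
#' @param ws a [window_set()] with the fitted window length.
#' @return Numeric matrix in the model's feature order.
#' @export
model_features <- function(object, ws) {
  stopifnot(inherits(object, "m5u_fit"), inherits(ws, "window_set"))
  if (ws$L != object$config$L)
    stop("window length does not match the fitted model", call. = FALSE)
  phys_args <- config_physchem_args(object$config, object$property_table)
  X_phys <- do.call(encode_windows, c(list(ws), phys_args))
  cbind(X_phys[, object$selection$best_features, drop = FALSE],
        embed_windows(ws, object$embedding))
}

#' Predict m5U sites for new windows
#'
#' @param object an [m5u_fit()] model.
#' @param newdata a [window_set()].
#' @param type `"class"` (0/1), `"score"` (signed decision value), or
#'   `"report"` (an [eval_report()]; requires labeled windows).
#' @param ... unused.
#' @return Per `type`: integer vector, numeric vector, or `eval_report`.
#' @export
predict.m5u_fit <- function(object, newdata,
                            type = c("class", "score", "report"), ...) {
  type <- match.arg(type)
  X <- model_features(object, newdata)
  if (type == "report") {
    s <- svm_scores(object$svm$model, X)
    return(eval_report(s$pred, window_labels(newdata), scores = s$scores))
  }
  predict(object$svm, X, type = type)
}

#' @export
print.m5u_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "m5U site prediction model (multi-view features + SVM)\n",
    "  training windows : %d (L = %d)\n",
    "  physicochemical  : %s\n",
    "  selection        : %s + IFS -> %d of %d features\n",
    "  embedding        : skip-gram k=%d, w=%d, dim=%d\n",
    "  SVM              : %s kernel, C=%g, gamma=%s\n",
    "  CV accuracy      : %.4f (%d-fold, fold-mean)\n"),
    length(x$train_ids), x$config$L,
    paste(x$config$views, collapse = " + "),
    x$ranking$method, x$selection$best_size, length(x$ranking$names),
    x$embedding$k, x$embedding$window, x$embedding$dim,
    x$config$svm$kernel, x$svm$C,
    if (is.numeric(x$svm$gamma)) format(x$svm$gamma) else x$svm$gamma,
    x$cv$mean["acc"], x$config$folds))
  invisible(x)
}

#' @export
summary.m5u_fit <- function(object, ...) {
  print(object)
  cat("\nFold-mean cross-validation metrics:\n")
  print(round(object$cv$mean, 4))
  cat("\nPooled confusion-matrix metrics:\n")
  print(object$cv$pooled)
  cat("\nTop 10 selected physicochemical features:\n")
  print(utils::head(data.frame(feature = object$ranking$names,
                               score = object$ranking$scores), 10))
  invisible(object)
}

#' @export
plot.m5u_fit <- function(x, which = c("ifs", "roc"), ...) {
  which <- match.arg(which)
  if (which == "ifs") {
    plot(x$selection, ...)
  } else {
    roc <- x$cv$pooled$roc
    graphics::plot(roc$fpr, roc$tpr, type = "l", xlab = "False positive rate",
                   ylab = "True positive rate",
                   main = sprintf("Pooled CV ROC (AUC = %.3f)", x$cv$pooled$auc),
                   ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Shapley interpretation of a fitted model
#'
#' Attributes the SVM decision score over the model's multi-view features
#' (the post-selection physicochemical features plus the embedding block)
#' for a subset of training samples, against a background drawn from the
#' training matrix. With more than 15 features (the usual case) the sampled
#' permutation estimator is used.
#'
#' @param object an [m5u_fit()] model.
#' @param n_samples how many training samples to explain (default 20).
#' @param n_background background rows (default 50).
#' @param n_perm permutation count for the sampled estimator.
#' @param seed integer seed for the subsampling.
#' @return A [shap_values()] result.
#' @export
interpret <- function(object, n_samples = 20, n_background = 50,
                      n_perm = 30, seed = 1) {
  stopifnot(inherits(object, "m5u_fit"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(object$X)
  take <- sample.int(n, min(n_samples, n))
  bg <- object$X[sample.int(n, min(n_background, n)), , drop = FALSE]
  model_fn <- function(M) {
    colnames(M) <- object$feature_names
    predict(object$svm, M, type = "score")
  }
  shap_values(model_fn, object$X[take, , drop = FALSE], background = bg,
              exact = FALSE, n_perm = n_perm, seed = seed)
}

#' Run the full pipeline and write a run directory
#'
#' Fits the model ([m5u_fit()]), optionally evaluates on an independent
#' test set, runs the composition analysis and the Shapley interpretation,
#' and writes every artifact (feature matrix, ranking + IFS curve,
#' embedding, CV and test reports, enrichment table, attribution summary)
#' plus a reproducibility manifest into `out_dir`.
#'
#' @param train labeled [window_set()].
#' @param config an [m5u_config()].
#' @param test optional labeled [window_set()] for independent testing.
#' @param out_dir output directory (created if needed).
#' @param shap_samples samples to explain in the interpretation stage
#'   (0 skips it).
#' @return The fitted `m5u_fit`, invisibly, with attribute `out_dir`.
#' @export
run_pipeline <- function(train, config = m5u_config(), test = NULL,
                         out_dir = tempfile("m5u_run_"), shap_samples = 10) {
  if (!is.null(test) && test$L != train$L)
    stop("test window length differs from training window length",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  fit <- stage("fit", m5u_fit(train, config))
  write_feature_tsv(fit$X, file.path(out_dir, "features.tsv"),
                    labels = train$windows$label)
  write_selection(fit$selection, file.path(out_dir, "selection.tsv"))
  write_embedding(fit$embedding, file.path(out_dir, "embedding.tsv"))
  jsonlite::write_json(
    list(fold_mean = as.list(fit$cv$mean),
         pooled = as.list(metric_vector(fit$cv$pooled)),
         C = fit$svm$C, gamma = fit$svm$gamma),
    file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)

  if (!is.null(test)) {
    rep <- stage("test", predict(fit, test, type = "report"))
    jsonlite::write_json(as.list(metric_vector(rep)),
                         file.path(out_dir, "test_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  lab <- train$windows$label
  if (all(c("positive", "negative") %in% lab)) {
    enr <- stage("composition",
                 enrichment(train[lab == "positive"], train[lab == "negative"]))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if (shap_samples > 0) {
    shap <- stage("interpret",
                  interpret(fit, n_samples = shap_samples, seed = config$seed))
    write_shap(shap, file.path(out_dir, "shap.tsv"),
               top_n = min(20, ncol(fit$X)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("m5usite")),
    r_version = R.version.string,
    seed = config$seed,
    n_train = length(train), n_test = if (is.null(test)) 0 else length(test),
    config = config[setdiff(names(config), "svm")],
    svm = unclass(config$svm),
    selected_features = fit$selection$best_size,
    chosen_C = fit$svm$C, chosen_gamma = fit$svm$gamma)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(fit, "out_dir") <- out_dir
  invisible(fit)
}
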