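# Binary-classification evaluation: confusion counts, Sn/Sp/Acc/MCC/
# precision/F1, ROC points by threshold sweep and trapezoidal AUC.

#' ROC curve and trapezoidal AUC from continuous scores
#'
#' Sweeps every distinct score as a threshold (ties grouped), producing a
#' curve that starts at (0,0) and ends at (1,1) with both coordinates
#' non-decreasing; AUC is the trapezoidal area under it. The AUC is
#' invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores, larger = more positive.
#' @param y 0/1 labels.
#' @return List with `roc` (data frame fpr/tpr) and `auc`.
#' @export
roc_curve <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  y <- as.integer(y)
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) stop("both classes required for a ROC curve",
                             call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  # group tied scores: cumulative counts at the end of each tie group
  last_of_group <- which(!duplicated(ss, fromLast = TRUE))
  tp <- cumsum(ys)[last_of_group]
  fp <- cumsum(1 - ys)[last_of_group]
  roc <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluation report from predictions and scores
#'
#' Computes the confusion matrix at the supplied hard predictions and the
#' full metric suite: Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n,
#' precision = TP/(TP+FP), F1 = 2 * precision * Sn / (precision + Sn),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), plus the ROC
#' curve and AUC from the continuous scores. Metrics with an undefined
#' denominator are reported as 0 and named in the `undefined` flag.
#'
#' @param pred 0/1 hard predictions.
#' @param y 0/1 true labels.
#' @param scores continuous decision scores (larger = more positive); if
#'   `NULL`, ROC/AUC are omitted.
#' @return An `eval_report` list: `tp,fp,tn,fn`, `sn,sp,acc,mcc,precision,f1`,
#'   `roc`, `auc`, `undefined`.
#' @examples
#' eval_report(c(1,1,0,0), c(1,0,1,0), scores = c(0.9, 0.6, 0.4, 0.1))
#' @export
eval_report <- function(pred, y, scores = NULL) {
  stopifnot(length(pred) == length(y))
  pred <- as.integer(pred); y <- as.integer(y)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  undefined <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  sn <- safe(tp, tp + fn, "sn")
  sp <- safe(tn, tn + fp, "sp")
  acc <- safe(tp + tn, tp + fp + tn + fn, "acc")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- if (precision + sn == 0) { undefined <- c(undefined, "f1"); 0 } else
    2 * precision * sn / (precision + sn)
  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 } else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  roc <- NULL; auc <- NA_real_
  if (!is.null(scores)) {
    r <- roc_curve(scores, y)
    roc <- r$roc; auc <- r$auc
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sn = sn, sp = sp, acc = acc, mcc = mcc,
                 precision = precision, f1 = f1,
                 roc = roc, auc = auc, undefined = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("<eval_report> n=%d (TP=%d FP=%d TN=%d FN=%d)\n",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  m <- c(Acc = x$acc, Sn = x$sn, Sp = x$sp, MCC = x$mcc,
         Precision = x$precision, F1 = x$f1, AUC = x$auc)
  print(round(m, digits))
  if (length(x$undefined))
    cat("undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Metric vector from an eval_report
#'
#' @param report an [eval_report()].
#' @return Named numeric vector (acc, sn, sp, mcc, precision, f1, auc).
#' @export
metric_vector <- function(report) {
  c(acc = report$acc, sn = report$sn, sp = report$sp, mcc = report$mcc,
    precision = report$precision, f1 = report$f1, auc = report$auc)
}
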