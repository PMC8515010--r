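#' Area under the ROC curve by pairwise concordance
#'
#' Exact Mann-Whitney formulation: the fraction of (positive, negative)
#' pairs in which the positive scores higher, counting ties as one half.
#'
#' @param scores numeric ranking scores (higher = more positive).
#' @param labels binary labels (logical, 0/1, or a two-level factor with the
#'   positive class given by \code{positive}).
#' @param positive value of \code{labels} treated as positive when labels are
#'   not logical/0-1.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels, positive = NULL) {
  if (length(scores) != length(labels)) stop("length mismatch")
  pos <- .asBinary(labels, positive)
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.asBinary <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  if (is.null(positive)) {
    if (all(labels %in% c("effective", "ineffective"))) positive <- "effective"
    else stop("supply 'positive' for non-standard labels")
  }
  labels == positive
}

#' Confusion-matrix evaluation report
#'
#' Standard binary classification metrics with the sensitive/effective class
#' as positive: accuracy, precision, recall (sensitivity), specificity,
#' support-weighted F1, and — when ranking scores are supplied — the ROC AUC
#' and curve points.
#'
#' @param predLabels,trueLabels equal-length binary label vectors.
#' @param scores optional ranking scores for AUC/ROC (higher = more positive).
#' @param positive positive-class value, see [rocAuc()].
#' @return An \code{"EvalReport"} list: accuracy, precision, recall,
#'   specificity, f1_weighted, auc, tp/fp/tn/fn, roc (data.frame of FPR/TPR).
#' @export
classificationMetrics <- function(predLabels, trueLabels, scores = NULL,
                                  positive = NULL) {
  if (length(predLabels) != length(trueLabels)) stop("length mismatch")
  p <- .asBinary(predLabels, positive)
  y <- .asBinary(trueLabels, positive)
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- function(tp, fp, fn) if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  f1pos <- f1(tp, fp, fn)
  f1neg <- f1(tn, fn, fp)   # negative class: swap roles
  f1w <- (f1pos * sum(y) + f1neg * sum(!y)) / length(y)
  out <- list(accuracy = (tp + tn) / length(y), precision = prec, recall = rec,
              specificity = spec, f1_weighted = f1w, auc = NA_real_,
              tp = tp, fp = fp, tn = tn, fn = fn, roc = NULL)
  if (!is.null(scores)) {
    out$auc <- rocAuc(scores, y)
    out$roc <- .rocPoints(scores, y)
  }
  structure(out, class = "EvalReport")
}

.rocPoints <- function(scores, pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    call <- scores >= t
    c(fpr = sum(call & !pos) / sum(!pos), tpr = sum(call & pos) / sum(pos))
  }, c(fpr = 0, tpr = 0)))
  rbind(data.frame(fpr = 0, tpr = 0), as.data.frame(pts), data.frame(fpr = 1, tpr = 1))
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf(paste0("EvalReport: accuracy %.3f, precision %.3f, recall %.3f, ",
                     "specificity %.3f, weighted F1 %.3f, AUC %s\n"),
              x$accuracy, x$precision, x$recall, x$specificity, x$f1_weighted,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat(sprintf("  confusion: TP %d FP %d TN %d FN %d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
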