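#' Confusion matrix
#'
#' K x K counts with rows indexing the true label and columns the
#' predicted label; the diagonal holds the per-class true positives. For
#' class i, FN is the off-diagonal sum of row i, FP the off-diagonal sum
#' of column i, and TN the remainder.
#'
#' @param truth,pred 0-based integer label vectors of equal length.
#' @param K number of classes.
#' @return an integer K x K matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, K) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  if (length(truth) != length(pred))
    .invalid_argument("truth and pred must have equal length")
  if (any(c(truth, pred) < 0L) || any(c(truth, pred) >= K))
    .invalid_argument("label out of range [0, K)")
  cm <- matrix(0L, K, K, dimnames = list(true = 0:(K - 1),
                                         pred = 0:(K - 1)))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * P * R / (P + R)`; defined as 0 when both inputs
#' are 0. Inputs may be proportions or percentages as long as they are
#' consistent; the result is on the same scale.
#'
#' @param precision,recall numeric values (scalars or vectors).
#' @return the F1 score(s).
#' @export
f1_from_pr <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

#' Evaluation metrics from a confusion matrix
#'
#' Computes overall accuracy (trace over total), per-class precision,
#' recall, F1 and intersection-over-union `TP / (TP + FP + FN)`, the mean
#' IoU across classes, and macro-averaged overall precision/recall/F1.
#' Undefined 0/0 ratios are reported as 0 and flagged.
#'
#' @param cm a [confusion_matrix()].
#' @return a `metrics_report` list: `accuracy`, `per_class` (data.frame
#'   with class, tp, fp, fn, tn, precision, recall, f1, iou, undefined),
#'   `miou`, `macro_precision`, `macro_recall`, `macro_f1`, `n`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  K <- nrow(cm)
  total <- sum(cm)
  if (total == 0) .invalid_argument("empty confusion matrix")
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- f1_from_pr(precision, recall)
  iou <- safe(tp, tp + fp + fn)
  undefined <- (tp + fp == 0) | (tp + fn == 0)
  per_class <- data.frame(class = 0:(K - 1), tp = tp, fp = fp, fn = fn,
                          tn = tn, precision = precision, recall = recall,
                          f1 = f1, iou = iou, undefined = undefined,
                          row.names = NULL)
  structure(list(accuracy = sum(tp) / total, per_class = per_class,
                 miou = mean(iou), macro_precision = mean(precision),
                 macro_recall = mean(recall), macro_f1 = mean(f1),
                 n = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | mIoU %.4f | macro P %.4f R %.4f F1 %.4f (n = %d)\n",
              x$accuracy, x$miou, x$macro_precision, x$macro_recall,
              x$macro_f1, x$n))
  print(format(x$per_class, digits = 4))
  invisible(x)
}

#' Write a metrics report and confusion matrix to files
#'
#' The report goes to JSON and CSV (per-class rows plus an overall row,
#' floats at 4 decimal places with raw counts alongside), the confusion
#' matrix to CSV.
#'
#' @param report a `metrics_report`.
#' @param cm a [confusion_matrix()].
#' @param prefix output path prefix; files `<prefix>_metrics.json`,
#'   `<prefix>_metrics.csv` and `<prefix>_confusion.csv` are written.
#' @return the written file paths, invisibly.
#' @export
write_metrics <- function(report, cm, prefix) {
  stopifnot(inherits(report, "metrics_report"))
  jsonlite::write_json(
    list(accuracy = report$accuracy, miou = report$miou,
         macro_precision = report$macro_precision,
         macro_recall = report$macro_recall, macro_f1 = report$macro_f1,
         n = report$n, per_class = report$per_class),
    paste0(prefix, "_metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  pc <- report$per_class
  num <- vapply(pc, is.numeric, logical(1)) &
    !names(pc) %in% c("class", "tp", "fp", "fn", "tn")
  pc[num] <- lapply(pc[num], round, 4)
  overall <- data.frame(class = "overall", tp = sum(pc$tp), fp = sum(pc$fp),
                        fn = sum(pc$fn), tn = sum(pc$tn),
                        precision = round(report$macro_precision, 4),
                        recall = round(report$macro_recall, 4),
                        f1 = round(report$macro_f1, 4),
                        iou = round(report$miou, 4), undefined = FALSE)
  pc$class <- as.character(pc$class)
  utils::write.csv(rbind(pc, overall), paste0(prefix, "_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(cm)),
                   paste0(prefix, "_confusion.csv"))
  invisible(paste0(prefix, c("_metrics.json", "_metrics.csv",
                             "_confusion.csv")))
}
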