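# Confusion matrix and multiclass accuracy / precision / recall / F1.

#' Confusion matrix
#'
#' `C[i, j]` counts instances whose true class is `i` and predicted class is
#' `j`, over a fixed class ordering.
#'
#' @param y_true,y_pred Equal-length vectors of labels drawn from
#'   `class_order`.
#' @param class_order Character vector fixing row/column order; defaults to
#'   the union of factor levels or observed labels.
#' @return Integer matrix with class dimnames, of class `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), class_order = c("0", "1"))
confusion_matrix <- function(y_true, y_pred, class_order = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_invalid("y_true and y_pred must have equal length")
  }
  if (is.null(class_order)) {
    class_order <- if (is.factor(y_true)) levels(y_true) else
      sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown)) {
    stop_invalid("labels outside class_order: ", paste(unknown, collapse = ", "))
  }
  cm <- table(
    factor(y_true, levels = class_order),
    factor(y_pred, levels = class_order)
  )
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(true = class_order, predicted = class_order)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`, on whatever scale (fraction or percent)
#' the inputs share; 0 when both are 0.
#'
#' @param precision,recall Nonnegative numerics (vectorised).
#' @return Numeric of the same length.
#' @export
#' @examples
#' f1_score(51.16, 26.51) # 34.92 (percent scale)
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Per-class one-vs-rest metrics
#'
#' Derives TP/FP/FN/TN per class from the confusion matrix and reports
#' precision, recall and F1 in percent, plus support. The `accuracy` column
#' repeats recall, the per-class convention used in activity-recognition
#' result tables. Divisions by zero yield 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame with one row per class: `class`, `support`, `tp`,
#'   `fp`, `fn`, `tn`, `accuracy`, `precision`, `recall`, `f1` (percent).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  cm <- unclass(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_ratio <- function(num, den, what) {
    zero <- den == 0
    if (any(zero)) {
      warning("zero denominator in ", what, " for class(es) ",
              paste(rownames(cm)[zero], collapse = ", "), "; reporting 0",
              call. = FALSE)
    }
    ifelse(zero, 0, num / den)
  }
  precision <- 100 * safe_ratio(tp, tp + fp, "precision")
  recall <- 100 * safe_ratio(tp, tp + fn, "recall")
  data.frame(
    class = rownames(cm),
    support = as.integer(rowSums(cm)),
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    accuracy = recall, # per-class accuracy reported as recall
    precision = precision,
    recall = recall,
    f1 = f1_score(precision, recall),
    row.names = NULL
  )
}

#' Overall (averaged) metrics
#'
#' Micro mode pools all one-vs-rest counts: for single-label multiclass
#' prediction this makes precision, recall and accuracy all equal to
#' `trace(cm) / total`. Weighted mode averages the per-class values with
#' support weights; zero-support classes are excluded with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param mode `"micro"` or `"weighted"`.
#' @return One-row data frame: `mode`, `accuracy`, `precision`, `recall`,
#'   `f1` (percent).
#' @export
overall_metrics <- function(cm, mode = c("micro", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (mode == "micro") {
    acc <- if (total == 0) 0 else 100 * sum(diag(unclass(cm))) / total
    return(data.frame(mode = "micro", accuracy = acc, precision = acc,
                      recall = acc, f1 = acc))
  }
  per <- per_class_metrics(cm)
  keep <- per$support > 0
  if (!all(keep)) {
    warning("excluding zero-support class(es) from weighted averages: ",
            paste(per$class[!keep], collapse = ", "), call. = FALSE)
  }
  w <- per$support[keep] / sum(per$support[keep])
  data.frame(
    mode = "weighted",
    accuracy = if (total == 0) 0 else 100 * sum(diag(unclass(cm))) / total,
    precision = sum(w * per$precision[keep]),
    recall = sum(w * per$recall[keep]),
    f1 = sum(w * per$f1[keep])
  )
}

#' Full evaluation report
#'
#' Bundles the confusion matrix, per-class table and both overall rows.
#'
#' @param y_true,y_pred Label vectors.
#' @param class_order Optional class ordering (see [confusion_matrix()]).
#' @return Object of class `metrics_report` with elements `confusion`,
#'   `per_class`, `overall` (micro and weighted rows).
#' @export
metrics_report <- function(y_true, y_pred, class_order = NULL) {
  cm <- confusion_matrix(y_true, y_pred, class_order)
  structure(
    list(
      confusion = cm,
      per_class = per_class_metrics(cm),
      overall = rbind(overall_metrics(cm, "micro"), overall_metrics(cm, "weighted"))
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat("Per-class metrics (%):\n")
  tab <- x$per_class[, c("class", "support", "accuracy", "precision", "recall", "f1")]
  tab[, 3:6] <- round(tab[, 3:6], digits)
  print(tab, row.names = FALSE)
  cat("\nOverall (%):\n")
  ov <- x$overall
  ov[, 2:5] <- round(ov[, 2:5], digits)
  print(ov, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to CSV files
#'
#' Writes `<prefix>_confusion.csv` (counts with class headers),
#' `<prefix>_per_class.csv` and `<prefix>_overall.csv`.
#'
#' @param report A [metrics_report()].
#' @param prefix Path prefix for the three files.
#' @return Character vector of the paths written, invisibly.
#' @export
write_metrics_csv <- function(report, prefix) {
  stopifnot(inherits(report, "metrics_report"))
  paths <- paste0(prefix, c("_confusion.csv", "_per_class.csv", "_overall.csv"))
  cm <- as.data.frame(unclass(report$confusion))
  cm <- cbind(true = rownames(cm), cm)
  utils::write.csv(cm, paths[1], row.names = FALSE)
  utils::write.csv(report$per_class, paths[2], row.names = FALSE)
  utils::write.csv(report$overall, paths[3], row.names = FALSE)
  invisible(paths)
}
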