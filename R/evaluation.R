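# Confusion matrices, weighted/macro classification metrics, and
# one-vs-rest ROC/AUC.

#' Confusion matrix from true and predicted labels
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted
#' as class `j` (0-based labels, rows = truth).
#'
#' @param y_true,y_pred integer labels in `0:(K-1)`.
#' @param K number of classes.
#' @param class_names optional class names.
#' @return an `endo_confusion` (K x K integer matrix with class names).
#' @export
confusion_matrix <- function(y_true, y_pred, K = 3L,
                             class_names = landmark_classes()) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  if (length(y_true) &&
      (min(c(y_true, y_pred)) < 0L || max(c(y_true, y_pred)) >= K))
    stop("labels must lie in [0, K)")
  cm <- matrix(0L, K, K, dimnames = list(true = class_names[seq_len(K)],
                                         predicted = class_names[seq_len(K)]))
  for (t in seq_along(y_true))
    cm[y_true[t] + 1L, y_pred[t] + 1L] <- cm[y_true[t] + 1L, y_pred[t] + 1L] + 1L
  structure(cm, class = c("endo_confusion", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class precision, recall and F1, plus accuracy, weighted averages
#' (class supports as weights) and macro averages (unweighted means).
#' Zero-division cases (empty predicted or true class) yield 0 with a
#' warning. Weighted recall always equals accuracy.
#'
#' @param cm an `endo_confusion` or plain K x K count matrix.
#' @return an `endossl_metrics` list.
#' @export
classification_metrics <- function(cm) {
  cm <- unclass(cm)
  K <- nrow(cm)
  total <- sum(cm)
  if (total == 0L) stop("confusion matrix is all zeros")
  support <- rowSums(cm)
  predicted <- colSums(cm)
  diagv <- diag(cm)
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
    if (any(den == 0))
      warning("zero division in ", what, " for class(es) ",
              paste(which(den == 0) - 1L, collapse = ", "),
              "; reporting 0")
    out
  }
  precision <- safe_div(diagv, predicted, "precision")
  recall <- safe_div(diagv, support, "recall")
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / total
  structure(list(
    accuracy = sum(diagv) / total,
    per_class = data.frame(class = rownames(cm) %||% as.character(seq_len(K) - 1L),
                           precision = precision, recall = recall, f1 = f1,
                           support = support, row.names = NULL),
    weighted_precision = sum(w * precision),
    weighted_recall = sum(w * recall),
    weighted_f1 = sum(w * f1),
    macro_precision = mean(precision),
    macro_recall = mean(recall),
    macro_f1 = mean(f1),
    confusion = cm), class = "endossl_metrics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.endossl_metrics <- function(x, digits = 2L, ...) {
  pct <- function(v) formatC(100 * v, format = "f", digits = digits)
  cat("Performance metrics\n")
  cat("  Accuracy             ", pct(x$accuracy), "\n")
  cat("  Weighted avg-Precision", pct(x$weighted_precision), "\n")
  cat("  Weighted avg-Recall   ", pct(x$weighted_recall), "\n")
  cat("  Weighted avg-F1-Score ", pct(x$weighted_f1), "\n")
  cat("  Macro avg-Precision   ", pct(x$macro_precision), "\n")
  cat("  Macro avg-Recall      ", pct(x$macro_recall), "\n")
  cat("  Macro avg-F1-Score    ", pct(x$macro_f1), "\n")
  if (!is.null(x$auc)) {
    cat("  Per-class AUC         ",
        paste(formatC(x$auc$per_class, format = "f", digits = 2L),
              collapse = " "), "\n")
    cat("  Macro AUC             ",
        formatC(x$auc$macro, format = "f", digits = 2L), "\n")
  }
  invisible(x)
}

#' One-vs-rest ROC AUC
#'
#' Per-class AUC by the rank statistic (Mann-Whitney U with midranks for
#' ties) of the class score against all other classes; the macro AUC is
#' the unweighted mean. A class absent from `y_true` gets `NA` and is
#' excluded from the macro average.
#'
#' @param y_true integer labels in `0:(K-1)`.
#' @param scores N x K matrix of class scores (not necessarily
#'   normalized).
#' @return list with `per_class` (length-K vector) and `macro`.
#' @export
roc_auc_ovr <- function(y_true, scores) {
  scores <- as.matrix(scores)
  stopifnot(length(y_true) == nrow(scores), all(is.finite(scores)))
  K <- ncol(scores)
  auc <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    pos <- y_true == (k - 1L)
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) next
    r <- rank(scores[, k])          # midranks for ties
    auc[k] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Evaluate a fitted model on the test side of a split
#'
#' @param model a fitted `endossl_model`.
#' @param manifest an `endo_manifest`.
#' @param split an `endo_split`; test indices are evaluated.
#' @return an `endossl_metrics` with an `auc` component.
#' @export
evaluate_model <- function(model, manifest, split) {
  idx <- split$test_indices
  if (length(idx) == 0L) stop("empty test split")
  x <- manifest_tensor(manifest, idx)
  y <- manifest_labels(manifest)[idx]
  pr <- predict(model, x, type = "prob")
  y_pred <- max.col(pr) - 1L
  m <- classification_metrics(confusion_matrix(y, y_pred, ncol(pr),
                                               model$class_names))
  m$auc <- roc_auc_ovr(y, pr)
  m
}

#' Write a metrics report to JSON and a markdown table
#' @param metrics an `endossl_metrics`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_metrics <- function(metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jpath <- file.path(dir, "metrics.json")
  payload <- list(accuracy = metrics$accuracy,
                  weighted_avg_precision = metrics$weighted_precision,
                  weighted_avg_recall = metrics$weighted_recall,
                  weighted_avg_f1 = metrics$weighted_f1,
                  macro_avg_precision = metrics$macro_precision,
                  macro_avg_recall = metrics$macro_recall,
                  macro_avg_f1 = metrics$macro_f1,
                  per_class = metrics$per_class,
                  confusion = metrics$confusion)
  if (!is.null(metrics$auc))
    payload$auc <- list(per_class = metrics$auc$per_class,
                        macro = metrics$auc$macro)
  jsonlite::write_json(payload, jpath, auto_unbox = TRUE, digits = NA)
  mpath <- file.path(dir, "metrics.md")
  pct <- function(v) formatC(100 * v, format = "f", digits = 2L)
  rows <- c(
    "| Performance metrics | Value |",
    "|---|---|",
    sprintf("| Accuracy | %s |", pct(metrics$accuracy)),
    sprintf("| Weighted avg-Precision | %s |", pct(metrics$weighted_precision)),
    sprintf("| Weighted avg-Recall | %s |", pct(metrics$weighted_recall)),
    sprintf("| Weighted avg-F1-Score | %s |", pct(metrics$weighted_f1)),
    sprintf("| Macro avg-Precision | %s |", pct(metrics$macro_precision)),
    sprintf("| Macro avg-Recall | %s |", pct(metrics$macro_recall)),
    sprintf("| Macro avg-F1-Score | %s |", pct(metrics$macro_f1)))
  writeLines(rows, mpath)
  invisible(c(jpath, mpath))
}

#' @export
plot.endo_confusion <- function(x, ...) {
  K <- nrow(x)
  graphics::image(seq_len(K), seq_len(K), t(unclass(x))[, K:1],
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True",
                  main = "Confusion matrix")
  graphics::axis(1, at = seq_len(K), labels = colnames(x), cex.axis = 0.8)
  graphics::axis(2, at = seq_len(K), labels = rev(rownames(x)), cex.axis = 0.8)
  for (i in seq_len(K)) for (j in seq_len(K))
    graphics::text(j, K + 1 - i, x[i, j])
  invisible(x)
}

#' ROC curves (one-vs-rest) for class scores
#' @param y_true integer labels.
#' @param scores N x K score matrix.
#' @param class_names class names for the legend.
#' @return invisibly, the per-class AUC.
#' @export
plot_roc_ovr <- function(y_true, scores, class_names = landmark_classes()) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  cols <- grDevices::hcl.colors(K, "Dark 3")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "False Positive Rate", ylab = "True Positive Rate",
                 main = "One-vs-rest ROC")
  auc <- roc_auc_ovr(y_true, scores)$per_class
  for (k in seq_len(K)) {
    pos <- y_true == (k - 1L)
    if (!any(pos) || all(pos)) next
    thr <- sort(unique(scores[, k]), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(scores[pos, k] >= t), 0)
    fpr <- vapply(thr, function(t) mean(scores[!pos, k] >= t), 0)
    graphics::lines(c(0, fpr, 1), c(0, tpr, 1), col = cols[k])
  }
  graphics::legend("bottomright",
                   sprintf("class %d (%s), AUC %.2f", seq_len(K) - 1L,
                           class_names[seq_len(K)], auc),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(auc)
}
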