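# Confusion matrices, per-class / aggregate metric reports, and rendered
# outputs (CSV, JSON, heatmap and bar-chart PNGs).

#' Confusion matrix from label sequences
#'
#' @param true_labels,predicted_labels equal-length integer vectors with
#'   0-based class indices in \[0, n_classes).
#' @param n_classes number of classes.
#' @param class_names optional class names (defaults to `class0..`).
#' @return object of class `confusion` — an n x n integer matrix, rows =
#'   true class, columns = predicted class.
#' @export
#' @examples
#' confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
confusion_matrix <- function(true_labels, predicted_labels, n_classes,
                             class_names = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop_invalid("label sequences must have equal length")
  all_lab <- c(true_labels, predicted_labels)
  if (length(all_lab) && (any(all_lab < 0) || any(all_lab >= n_classes)))
    stop_invalid("labels must lie in [0, %d)", n_classes)
  class_names <- class_names %||% paste0("class", seq_len(n_classes) - 1)
  cm <- table(factor(true_labels, levels = 0:(n_classes - 1)),
              factor(predicted_labels, levels = 0:(n_classes - 1)))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = class_names, predicted = class_names))
  structure(cm, class = c("confusion", "matrix", "array"))
}

#' Per-class and aggregate classification metrics
#'
#' For class j: precision = cm\[j, j\] / colsum_j, recall = cm\[j, j\] /
#' rowsum_j, F1 = their harmonic mean; a zero denominator yields 0 by
#' convention. Macro averages are unweighted means over classes; weighted
#' averages are support-weighted means (so weighted recall equals overall
#' accuracy exactly). Values are kept at full precision; rendering rounds
#' half-up to 2 decimals.
#'
#' @param cm a confusion matrix (rows = true, columns = predicted).
#' @return object of class `classification_report`: list with `per_class`
#'   (data frame: precision, recall, f1, support), `macro`, `weighted`,
#'   `accuracy`, `total`.
#' @export
classification_report <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0)
    stop(structure(class = c("lbpfuse_empty_evaluation", "error", "condition"),
                   list(message = "cannot report on an all-zero confusion matrix",
                        call = sys.call())))
  support <- rowSums(cm)
  colsum <- colSums(cm)
  tp <- diag(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, colsum)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  wmean <- function(v) sum(v * support) / total
  cls <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)) - 1)
  structure(list(
    per_class = data.frame(class = cls, precision = precision, recall = recall,
                           f1 = f1, support = as.integer(support),
                           row.names = NULL, stringsAsFactors = FALSE),
    macro = c(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted = c(precision = wmean(precision), recall = wmean(recall), f1 = wmean(f1)),
    accuracy = sum(tp) / total,
    total = as.integer(total)),
    class = "classification_report")
}

# report as the rendered 8-row table (5 class rows + macro/weighted/accuracy)
.report_table <- function(report, digits = NULL) {
  rnd <- if (is.null(digits)) identity else function(x) round_half_up(x, digits)
  pc <- report$per_class
  rbind(
    data.frame(class = pc$class, precision = rnd(pc$precision),
               recall = rnd(pc$recall), f1 = rnd(pc$f1), support = pc$support),
    data.frame(class = "macro avg", precision = rnd(report$macro["precision"]),
               recall = rnd(report$macro["recall"]), f1 = rnd(report$macro["f1"]),
               support = report$total),
    data.frame(class = "weighted avg", precision = rnd(report$weighted["precision"]),
               recall = rnd(report$weighted["recall"]),
               f1 = rnd(report$weighted["f1"]), support = report$total),
    data.frame(class = "accuracy", precision = NA, recall = NA,
               f1 = rnd(report$accuracy), support = report$total))
}

#' @export
print.classification_report <- function(x, digits = 2, ...) {
  cat(sprintf("classification report (%d samples, accuracy %s)\n",
              x$total, format(round_half_up(x$accuracy, digits))))
  print(.report_table(x, digits), row.names = FALSE)
  invisible(x)
}

#' Render a report to CSV, JSON and PNG files
#'
#' Writes `report.csv` (full precision, 5 class rows plus macro / weighted /
#' accuracy rows), `report.json`, a confusion-matrix heatmap
#' (`confusion.png`) and a per-metric bar chart (`metrics.png`).
#'
#' @param report a `classification_report`.
#' @param cm the confusion matrix it was computed from.
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(report, cm, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop(structure(class = c("lbpfuse_io_error", "error", "condition"),
                   list(message = sprintf("cannot write to directory '%s'", out_dir),
                        call = sys.call())))
  files <- file.path(out_dir, c("report.csv", "report.json", "confusion.png",
                                "metrics.png"))
  write.csv(.report_table(report), files[1], row.names = FALSE)
  jsonlite::write_json(list(per_class = report$per_class,
                            macro = as.list(report$macro),
                            weighted = as.list(report$weighted),
                            accuracy = report$accuracy, total = report$total),
                       files[2], auto_unbox = TRUE, digits = NA)

  m <- unclass(cm)
  n <- nrow(m)
  grDevices::png(files[3], width = 640, height = 560)
  par(mar = c(7, 7, 3, 1))
  image(1:n, 1:n, t(m[n:1, , drop = FALSE]), col = hcl.colors(64, "Blues 3", rev = TRUE),
        axes = FALSE, xlab = "", ylab = "", main = "Confusion matrix")
  axis(1, at = 1:n, labels = colnames(m), las = 2)
  axis(2, at = n:1, labels = rownames(m), las = 2)
  mtext("predicted", side = 1, line = 5.5); mtext("true", side = 2, line = 5.5)
  for (i in 1:n) for (j in 1:n)
    text(j, n + 1 - i, m[i, j],
         col = if (m[i, j] > max(m) / 2) "white" else "black")
  dev.off()

  pc <- report$per_class
  grDevices::png(files[4], width = 720, height = 480)
  bar <- t(as.matrix(pc[, c("precision", "recall", "f1")]))
  colnames(bar) <- pc$class
  barplot(bar, beside = TRUE, ylim = c(0, 1.05), col = gray(c(0.2, 0.5, 0.8)),
          las = 2, main = "Per-class metrics")
  legend("bottomright", legend = c("precision", "recall", "F1"),
         fill = gray(c(0.2, 0.5, 0.8)), bg = "white")
  dev.off()

  invisible(files)
}

#' Evaluate a model on a labeled split
#'
#' Runs the resize-only (no augmentation) pipeline on every item, predicts,
#' and assembles the confusion matrix and classification report.
#'
#' @param model a `fusion_model`.
#' @param set a `labeled_image_set` (e.g. the test split).
#' @param batch_size inference batch size.
#' @param images optional pre-loaded decoded image list parallel to
#'   `set$items`.
#' @return list with `report`, `cm`, `pred` (0-based predictions), `truth`.
#' @export
evaluate_model <- function(model, set, batch_size = 8, images = NULL) {
  imgs <- images %||% load_dataset(set)
  probs <- .predict_arrays(model, imgs, batch_size)
  pred <- max.col(probs, ties.method = "first") - 1L
  cm <- confusion_matrix(set$items$class, pred, length(set$class_names),
                         set$class_names)
  list(report = classification_report(cm), cm = cm, pred = pred,
       truth = set$items$class)
}
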