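# One-call model fitting: discover -> split -> train -> test evaluation,
# returning a single fitted-model object with the usual methods.

#' Fit a dual-branch fusion classifier to a folder-per-class dataset
#'
#' Convenience front end tying the whole pipeline together: discovers the
#' dataset, performs the seeded stratified 70/15/15 split, trains the
#' configured variant, selects the best-validation-accuracy checkpoint, and
#' evaluates it on the held-out test split.
#'
#' @param root dataset directory (one folder per class), or a
#'   `labeled_image_set`.
#' @param model a [fusion_config()] (use `backbone_name = "tiny_cnn",
#'   pretrained = FALSE` for fully offline runs).
#' @param train a [train_config()].
#' @param fractions train/val/test fractions.
#' @param augment an [augmentation_config()] (defaults to the standard
#'   recipe at the model input size).
#' @param verbose print per-epoch progress.
#' @return object of class `lbpfuse_fit` with components `model` (best
#'   checkpoint `fusion_model`), `logs`, `best_epoch`, `test` (report,
#'   confusion matrix and predictions on the test split), `splits`.
#' @export
#' @examples
#' \donttest{
#' dir <- tempfile()
#' generate_eye_fixture(dir, n_per_class = 4)
#' fit <- lbpfuse_fit(dir,
#'                    model = fusion_config(backbone_name = "tiny_cnn",
#'                                          pretrained = FALSE),
#'                    train = train_config(epochs = 2, seed = 7))
#' print(fit)
#' }
lbpfuse_fit <- function(root,
                        model = fusion_config(),
                        train = train_config(),
                        fractions = c(0.70, 0.15, 0.15),
                        augment = augmentation_config(size = model$input_size),
                        verbose = FALSE) {
  set <- if (inherits(root, "labeled_image_set")) root else discover_dataset(root)
  if (length(set$class_names) != model$n_classes)
    .config_error("model is configured for %d classes but the dataset has %d",
                  model$n_classes, length(set$class_names))
  splits <- stratified_split(set, fractions, train$seed)
  net <- build_variant(model, seed = train$seed, class_names = set$class_names)
  res <- train_model(net, splits, train, augment, verbose = verbose)
  test <- evaluate_model(res$model, splits$test, train$batch_size)
  structure(list(model = res$model, final = res$final, logs = res$logs,
                 best_epoch = res$best_epoch, test = test, splits = splits,
                 train_config = train, call = match.call()),
            class = "lbpfuse_fit")
}

#' @export
print.lbpfuse_fit <- function(x, ...) {
  cat("Dual-branch fusion classifier fit\n")
  print(x$model)
  cat(sprintf("epochs: %d (best checkpoint at %d);  test accuracy: %.3f\n",
              nrow(x$logs), x$best_epoch, x$test$report$accuracy))
  invisible(x)
}

#' @export
summary.lbpfuse_fit <- function(object, ...) {
  print(object)
  cat("\nTest-split report:\n")
  print(object$test$report)
  invisible(object)
}

#' @export
coef.lbpfuse_fit <- function(object, ...) {
  flatten_leaves(.trainable(object$model$params))
}

#' @export
predict.lbpfuse_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' Plot training history or the test confusion matrix
#'
#' @param x an `lbpfuse_fit`.
#' @param type `"history"` (loss / accuracy curves by epoch) or
#'   `"confusion"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.lbpfuse_fit <- function(x, type = c("history", "confusion"), ...) {
  type <- match.arg(type)
  if (type == "history") {
    op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1)); on.exit(par(op))
    plot(x$logs$epoch, x$logs$train_loss, type = "l", xlab = "epoch",
         ylab = "loss", main = "loss")
    lines(x$logs$epoch, x$logs$val_loss, lty = 2)
    legend("topright", c("train", "val"), lty = 1:2, bty = "n")
    plot(x$logs$epoch, x$logs$train_acc, type = "l", ylim = c(0, 1),
         xlab = "epoch", ylab = "accuracy", main = "accuracy")
    lines(x$logs$epoch, x$logs$val_acc, lty = 2)
    abline(v = x$best_epoch, col = "grey")
  } else {
    m <- unclass(x$test$cm); n <- nrow(m)
    image(1:n, 1:n, t(m[n:1, ]), col = hcl.colors(64, "Blues 3", rev = TRUE),
          axes = FALSE, xlab = "predicted", ylab = "true",
          main = "test confusion")
    axis(1, at = 1:n, labels = colnames(m), las = 2)
    axis(2, at = n:1, labels = rownames(m), las = 2)
    for (i in 1:n) for (j in 1:n) text(j, n + 1 - i, m[i, j])
  }
  invisible(x)
}
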