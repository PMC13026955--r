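# Training engine: Adam over two differential-learning-rate parameter
# groups, cross-entropy loss, cosine-annealed schedule stepped once per
# epoch, per-epoch logging, and best-validation-accuracy checkpointing.

#' Training configuration
#'
#' Defaults follow the reference protocol: 25 epochs, batch size 8, Adam with
#' 0.0002 for the pretrained backbone and 0.002 for the texture branch and
#' classifier head, cosine annealing with T_max = 25 and eta_min = 0. Adam
#' moments are the library-standard (0.9, 0.999), eps 1e-8, no weight decay,
#' no gradient clipping.
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param lr_backbone backbone learning rate.
#' @param lr_new texture-branch / head learning rate.
#' @param t_max cosine annealing period in epochs.
#' @param eta_min final learning rate of the schedule.
#' @param seed master seed for shuffling, augmentation and initialisation.
#' @param deterministic seed all randomness so two runs are identical.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 25, batch_size = 8, lr_backbone = 2e-4,
                         lr_new = 2e-3, t_max = 25, eta_min = 0,
                         seed = 42L, deterministic = TRUE) {
  if (epochs < 1) .config_error("epochs must be >= 1")
  if (lr_backbone <= 0 || lr_new <= 0) .config_error("learning rates must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_backbone = lr_backbone, lr_new = lr_new,
                 t_max = as.integer(t_max), eta_min = eta_min,
                 seed = as.integer(seed), deterministic = deterministic),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' eta(t) = eta_min + (base - eta_min) (1 + cos(pi t / t_max)) / 2 for epoch
#' index t in \[0, t_max\]; the rate starts at `base` and decays to `eta_min`.
#'
#' @param base base learning rate.
#' @param t epoch index (0-based).
#' @param t_max annealing period.
#' @param eta_min floor rate (default 0).
#' @return the scheduled rate.
#' @export
#' @examples
#' cosine_lr(0.002, 5, 25)  # 0.001809017
cosine_lr <- function(base, t, t_max, eta_min = 0) {
  if (any(t < 0) || any(t > t_max))
    stop_invalid("epoch index t must lie in [0, t_max = %s]", t_max)
  eta_min + 0.5 * (base - eta_min) * (1 + cos(pi * t / t_max))
}

#' Select the best checkpoint epoch
#'
#' The retained checkpoint maximises validation accuracy; ties go to the
#' earlier epoch.
#'
#' @param logs data frame of epoch logs with a `val_acc` column, or a numeric
#'   vector of validation accuracies.
#' @return 1-based epoch index.
#' @export
#' @examples
#' select_checkpoint(c(0.5, 0.9, 0.7))  # 2
#' select_checkpoint(c(0.8, 0.8))       # 1
select_checkpoint <- function(logs) {
  acc <- if (is.data.frame(logs)) logs$val_acc else logs
  if (length(acc) < 1) stop_invalid("need at least one completed epoch")
  which.max(acc)
}

# ---- Adam over parameter paths --------------------------------------------

get_path <- function(x, path) {
  for (p in strsplit(path, "/", fixed = TRUE)[[1]]) x <- x[[p]]
  x
}

set_path <- function(x, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, p) call("[[", acc, p), parts, quote(x))
  eval(call("<-", expr, quote(value)))
  x
}

adam_init <- function(paths) {
  list(t = 0L,
       m = stats::setNames(vector("list", length(paths)), paths),
       v = stats::setNames(vector("list", length(paths)), paths))
}

adam_step <- function(params, grads, state, lr_by_path,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (path in names(lr_by_path)) {
    g <- get_path(grads, path)
    if (is.null(g)) next
    m <- state$m[[path]]; v <- state$v[[path]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    state$m[[path]] <- m; state$v[[path]] <- v
    upd <- lr_by_path[[path]] * (m / bc1) / (sqrt(v / bc2) + eps)
    params <- set_path(params, path, get_path(params, path) - upd)
  }
  list(params = params, state = state)
}

# ---- batch assembly --------------------------------------------------------

# Build (rgb, lbp, labels) batch arrays from decoded images.
.assemble_batch <- function(model, imgs, labels0, aug_cfg) {
  s <- model$config$input_size
  duals <- lapply(imgs, function(im) prepare_dual(augment_image(im, aug_cfg)))
  rgb <- if (model$config$variant != "lbp_only")
    array(unlist(lapply(duals, `[[`, "rgb")), c(s, s, 3, length(imgs)))
  lbp <- if (model$config$variant != "rgb_only")
    array(unlist(lapply(duals, `[[`, "lbp")), c(s, s, 1, length(imgs)))
  list(rgb = rgb, lbp = lbp, labels = labels0 + 1L)
}

.eval_batches <- function(model, batches, pool = NULL) {
  loss <- 0; correct <- 0; n <- 0; pred <- integer(0)
  for (b in batches) {
    fw <- fusion_forward(model, b$rgb, b$lbp, train = FALSE,
                         want_cache = !is.null(pool), pool = pool)
    ce <- cross_entropy(fw$logits, b$labels)
    k <- length(b$labels)
    loss <- loss + ce$loss * k
    p <- max.col(t(fw$logits), ties.method = "first")
    pred <- c(pred, p)
    correct <- correct + sum(p == b$labels)
    n <- n + k
  }
  list(loss = loss / n, acc = correct / n, pred = pred - 1L)
}

#' Train a fusion model
#'
#' Runs Adam over the two differential-learning-rate groups with
#' cross-entropy loss. The cosine schedule is stepped once per epoch and both
#' groups decay proportionally (their ratio stays constant). Training images
#' are re-augmented — and their LBP plane recomputed — every epoch;
#' validation uses the resize-only pipeline. The checkpoint with the best
#' validation accuracy (ties: earliest epoch) is retained.
#'
#' @param model a `fusion_model` from [build_variant()].
#' @param splits result of [stratified_split()] (components `train`, `val`).
#' @param config a [train_config()].
#' @param augment an [augmentation_config()]; its `size` must equal the model
#'   input size.
#' @param images optional pre-loaded decoded images, a list with components
#'   `train` and `val` parallel to the split items (loaded from disk when
#'   omitted).
#' @param verbose print a per-epoch summary line to stderr.
#' @return list of class `train_result`: `model` (best checkpoint), `final`
#'   (last epoch), `logs` (one row per epoch: losses, accuracies and the two
#'   learning rates), `best_epoch`.
#' @export
train_model <- function(model, splits, config = train_config(),
                        augment = augmentation_config(size = model$config$input_size),
                        images = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "fusion_model"), inherits(config, "train_config"))
  if (nrow(splits$train$items) == 0 || nrow(splits$val$items) == 0)
    .config_error("training and validation splits must be non-empty")
  if (augment$size != model$config$input_size)
    .config_error("augmentation size %d does not match model input size %d",
                  augment$size, model$config$input_size)
  if (is.null(model$class_names)) model$class_names <- splits$train$class_names

  groups <- parameter_groups(model, config$lr_backbone, config$lr_new)
  train_imgs <- images$train %||% load_dataset(splits$train)
  val_imgs <- images$val %||% load_dataset(splits$val)
  labels_tr <- splits$train$items$class
  eval_aug <- augmentation_config(size = augment$size, enabled = FALSE)

  with_seed(config$seed, {
    # validation pipeline is deterministic; assemble once
    val_batches <- local({
      idx <- split(seq_along(val_imgs),
                   ceiling(seq_along(val_imgs) / config$batch_size))
      lapply(idx, function(ii)
        .assemble_batch(model, val_imgs[ii], splits$val$items$class[ii], eval_aug))
    })

    adam <- adam_init(unlist(lapply(groups, `[[`, "paths")))
    cache_pool <- new.env(parent = emptyenv())  # reuse C++ buffers across batches
    logs <- NULL
    best <- list(acc = -Inf, epoch = 0L, params = NULL, state = NULL)

    for (epoch in seq_len(config$epochs)) {
      t_sched <- min(epoch - 1L, config$t_max)
      lrs <- vapply(groups, function(g)
        cosine_lr(g$lr, t_sched, config$t_max, config$eta_min), numeric(1))
      lr_by_path <- stats::setNames(
        rep(unname(lrs), times = vapply(groups, function(g) length(g$paths), integer(1))),
        unlist(lapply(groups, `[[`, "paths")))

      ord <- sample.int(length(train_imgs))
      bidx <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_correct <- 0; ep_n <- 0
      for (bi in seq_along(bidx)) {
        ii <- bidx[[bi]]
        b <- .assemble_batch(model, train_imgs[ii], labels_tr[ii], augment)
        fw <- fusion_forward(model, b$rgb, b$lbp, train = TRUE, want_cache = TRUE,
                             pool = cache_pool)
        model <- fw$model   # running BN statistics
        ce <- cross_entropy(fw$logits, b$labels)
        if (!is.finite(ce$loss))
          stop(sprintf("non-finite training loss at epoch %d, batch %d", epoch, bi))
        grads <- fusion_backward(model, fw$cache, ce$glogits)
        upd <- adam_step(model$params, grads, adam, lr_by_path)
        model$params <- upd$params
        adam <- upd$state
        ep_loss <- ep_loss + ce$loss * length(ii)
        ep_correct <- ep_correct +
          sum(max.col(t(fw$logits), ties.method = "first") == b$labels)
        ep_n <- ep_n + length(ii)
      }

      val <- .eval_batches(model, val_batches, pool = cache_pool)
      logs <- rbind(logs, data.frame(
        epoch = epoch, train_loss = ep_loss / ep_n, train_acc = ep_correct / ep_n,
        val_loss = val$loss, val_acc = val$acc,
        lr_backbone = if ("backbone" %in% names(groups)) lrs[["backbone"]] else NA_real_,
        lr_new = lrs[["new"]]))
      if (verbose)
        message(sprintf("epoch %2d/%d  loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, config$epochs, ep_loss / ep_n, ep_correct / ep_n,
                        val$loss, val$acc))
      if (val$acc > best$acc) {
        best <- list(acc = val$acc, epoch = epoch,
                     params = model$params, state = model$state)
      }
    }

    best_model <- model
    best_model$params <- best$params
    best_model$state <- best$state
    structure(list(model = best_model, final = model, logs = logs,
                   best_epoch = best$epoch, config = config),
              class = "train_result")
  })
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("training run: %d epochs, best validation accuracy %.3f at epoch %d\n",
              nrow(x$logs), max(x$logs$val_acc), x$best_epoch))
  print(utils::tail(x$logs, 3), row.names = FALSE)
  invisible(x)
}
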