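# Dual-branch fusion network assembly.
#
# The full model pairs a pretrained-style RGB backbone (consumed through a
# registry contract; a compact stand-in CNN is bundled for offline use) with
# a bespoke texture branch that reads the rescaled uniform-LBP plane:
# three (conv 3x3 pad 1 -> BN -> ReLU -> maxpool 2x2) blocks widening
# 1 -> 16 -> 32 -> 64, a squeeze-and-excitation gate (64 -> 4 -> 64), and
# adaptive average pooling to 4x4, flattened to a 1024-d vector. Branch
# features are concatenated (mid-level fusion) and classified by a single
# affine head. Ablation variants: rgb_only, lbp_only, no_se, full.

.backbones <- new.env(parent = emptyenv())

#' Register a backbone in the model registry
#'
#' A backbone entry declares its pooled feature dimension and, when it can be
#' constructed offline, a builder. The default `"efficientnetv2_s"` entry is
#' metadata-only: it fixes the 1792-d feature contract used by the fusion
#' arithmetic, but constructing it requires downloaded pretrained weights,
#' which this package does not bundle.
#'
#' @param name identifier string.
#' @param feature_dim pooled feature dimension the backbone emits.
#' @param builder `NULL`, or `function(feature_dim)` returning a parameter
#'   list for [build_rgb_branch()].
#' @param pretrained_available whether pretrained weights can be loaded.
#' @return the registry entry, invisibly.
#' @export
register_backbone <- function(name, feature_dim, builder = NULL,
                              pretrained_available = FALSE) {
  entry <- list(name = name, feature_dim = as.integer(feature_dim),
                builder = builder, pretrained_available = pretrained_available)
  assign(name, entry, envir = .backbones)
  invisible(entry)
}

#' List registered backbone names
#' @return character vector of identifiers.
#' @export
list_backbones <- function() sort(ls(.backbones))

.backbone_entry <- function(name) {
  if (!exists(name, envir = .backbones))
    stop(structure(class = c("lbpfuse_config_error", "error", "condition"),
                   list(message = sprintf(
                     "unknown backbone '%s'; registered backbones: %s",
                     name, paste(list_backbones(), collapse = ", ")),
                     call = sys.call(-1))))
  get(name, envir = .backbones)
}

# conv block parameters: weight U(+-sqrt(1/fan_in)), bias 0, BN affine (1, 0)
.conv_block_params <- function(cin, cout) {
  bound <- sqrt(1 / (9 * cin))
  list(w = array(runif(9 * cin * cout, -bound, bound), c(3, 3, cin, cout)),
       b = numeric(cout), gamma = rep(1, cout), beta = numeric(cout))
}

.conv_block_state <- function(cout) list(mean = numeric(cout), var = rep(1, cout))

.name_blocks <- function(blocks) stats::setNames(blocks, paste0("b", seq_along(blocks)))

# Stand-in backbone: 4x4 average pool (224 -> 56) then three conv blocks
# 3 -> 16 -> 32 -> feature_dim (56 -> 28 -> 14 -> 7), global average pool.
.tiny_builder <- function(feature_dim) {
  widths <- c(3L, 16L, 32L, as.integer(feature_dim))
  list(kind = "tiny_cnn",
       input_pool = 56L,
       widths = widths,
       blocks = .name_blocks(lapply(1:3, function(i)
         .conv_block_params(widths[i], widths[i + 1]))))
}

.init_registry <- function() {
  register_backbone("efficientnetv2_s", 1792L, builder = NULL,
                    pretrained_available = FALSE)
  register_backbone("tiny_cnn", 32L, builder = .tiny_builder,
                    pretrained_available = FALSE)
}

.onLoad <- function(libname, pkgname) .init_registry()

.config_error <- function(fmt, ...) {
  stop(structure(class = c("lbpfuse_config_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Fusion architecture configuration
#'
#' Captures every architecture hyperparameter of the dual-branch model. Under
#' the defaults the texture branch emits `lbp_channels[3] * lbp_pool_size^2 =
#' 1024` features, the declared RGB feature dimension is 1792
#' (EfficientNetV2-S contract), and the fused head input is 2816.
#'
#' @param n_classes number of target classes (default 5).
#' @param variant one of `"full"`, `"rgb_only"`, `"lbp_only"`, `"no_se"`.
#' @param backbone_name registered backbone identifier.
#' @param pretrained load pretrained backbone weights (requires a download;
#'   the bundled stand-in has none).
#' @param rgb_feature_dim override of the backbone feature dimension; by
#'   default resolved from the registry.
#' @param lbp_channels widths of the three texture-branch conv layers.
#' @param se_reduction SE bottleneck reduction ratio; must divide
#'   `lbp_channels[3]`.
#' @param lbp_pool_size adaptive pooling size of the texture branch.
#' @param input_size square input size in pixels.
#' @return object of class `fusion_config`.
#' @export
#' @examples
#' cfg <- fusion_config(backbone_name = "tiny_cnn", pretrained = FALSE)
#' fusion_dims(fusion_config())  # rgb 1792, lbp 1024, fused 2816
fusion_config <- function(n_classes = 5,
                          variant = c("full", "rgb_only", "lbp_only", "no_se"),
                          backbone_name = "efficientnetv2_s",
                          pretrained = TRUE,
                          rgb_feature_dim = NULL,
                          lbp_channels = c(16L, 32L, 64L),
                          se_reduction = 16,
                          lbp_pool_size = 4,
                          input_size = 224) {
  variant <- match.arg(variant)
  entry <- .backbone_entry(backbone_name)
  rgb_feature_dim <- as.integer(rgb_feature_dim %||% entry$feature_dim)
  if (length(lbp_channels) != 3 || any(lbp_channels <= 0))
    .config_error("lbp_channels must be three positive widths")
  if (lbp_channels[3] %% se_reduction != 0)
    .config_error("se_reduction %d must divide the final texture width %d",
                  se_reduction, lbp_channels[3])
  if (input_size %% 8 != 0 || input_size < 8 * lbp_pool_size)
    .config_error("input_size must be a multiple of 8 and at least %d",
                  8 * lbp_pool_size)
  structure(list(n_classes = as.integer(n_classes), variant = variant,
                 backbone_name = backbone_name, pretrained = pretrained,
                 rgb_feature_dim = rgb_feature_dim,
                 lbp_channels = as.integer(lbp_channels),
                 se_reduction = as.integer(se_reduction),
                 lbp_pool_size = as.integer(lbp_pool_size),
                 input_size = as.integer(input_size)),
            class = "fusion_config")
}

#' Branch and fused feature dimensions implied by a configuration
#'
#' @param cfg a `fusion_config`.
#' @return list with `rgb`, `lbp`, and `fused` (the classifier-head input
#'   dimension of the configured variant).
#' @export
fusion_dims <- function(cfg) {
  lbp <- cfg$lbp_channels[3] * cfg$lbp_pool_size^2
  fused <- switch(cfg$variant,
                  rgb_only = cfg$rgb_feature_dim,
                  lbp_only = lbp,
                  cfg$rgb_feature_dim + lbp)
  list(rgb = cfg$rgb_feature_dim, lbp = lbp, fused = fused)
}

#' Build the texture-branch parameters
#'
#' Three (conv 3x3 pad 1, BN, ReLU, maxpool 2x2) blocks with widths
#' 1 -> 16 -> 32 -> 64, an SE gate (identity for the `no_se` variant), and
#' adaptive average pooling to `lbp_pool_size`^2 cells.
#'
#' @param cfg a `fusion_config`.
#' @return parameter list (component `se` is `NULL` for `no_se`).
#' @export
build_texture_branch <- function(cfg) {
  widths <- c(1L, cfg$lbp_channels)
  list(blocks = .name_blocks(lapply(1:3, function(i)
         .conv_block_params(widths[i], widths[i + 1]))),
       se = if (cfg$variant == "no_se") NULL else
         unclass(se_params(cfg$lbp_channels[3], cfg$se_reduction)))
}

#' Build the RGB-branch (backbone) parameters
#'
#' Resolves `cfg$backbone_name` in the registry. With `pretrained = TRUE` the
#' backbone must have loadable pretrained weights; no backbone is ever
#' silently randomly initialised in that case.
#'
#' @param cfg a `fusion_config`.
#' @return parameter list with the backbone structure and `feature_dim`.
#' @export
build_rgb_branch <- function(cfg) {
  entry <- .backbone_entry(cfg$backbone_name)
  if (cfg$pretrained && !entry$pretrained_available)
    stop(structure(class = c("lbpfuse_download_required", "error", "condition"),
                   list(message = sprintf(
      paste0("backbone '%s' requires pretrained weights that must be downloaded; ",
             "none are bundled. Use pretrained = FALSE with a buildable backbone ",
             "(e.g. 'tiny_cnn') for offline runs."), cfg$backbone_name),
      call = sys.call())))
  if (is.null(entry$builder))
    .config_error(paste0("backbone '%s' is registered as a feature contract only ",
                         "and cannot be constructed offline; buildable backbones: %s"),
                  cfg$backbone_name,
                  paste(Filter(function(n) !is.null(.backbone_entry(n)$builder),
                               list_backbones()), collapse = ", "))
  dim <- cfg$rgb_feature_dim %||% entry$feature_dim
  c(entry$builder(dim), list(feature_dim = as.integer(dim)))
}

#' Assemble a model variant
#'
#' Builds the configured variant: `rgb_only` drops the texture branch,
#' `lbp_only` drops the backbone, `no_se` replaces the texture SE gate with
#' the identity, `full` is the proposed dual-branch model. Initialisation is
#' seeded; two builds with the same seed are bit-identical.
#'
#' @param cfg a `fusion_config`.
#' @param seed integer seed for parameter initialisation.
#' @param class_names optional character vector of length `n_classes`.
#' @return object of class `fusion_model`.
#' @export
build_variant <- function(cfg, seed = 1L, class_names = NULL) {
  stopifnot(inherits(cfg, "fusion_config"))
  if (!is.null(class_names) && length(class_names) != cfg$n_classes)
    .config_error("expected %d class names, got %d", cfg$n_classes, length(class_names))
  dims <- fusion_dims(cfg)
  with_seed(seed, {
    backbone <- if (cfg$variant != "lbp_only") build_rgb_branch(cfg) else NULL
    texture <- if (cfg$variant != "rgb_only") build_texture_branch(cfg) else NULL
    hb <- sqrt(1 / dims$fused)
    head <- list(w = matrix(runif(cfg$n_classes * dims$fused, -hb, hb),
                            cfg$n_classes, dims$fused),
                 b = numeric(cfg$n_classes))
    state <- list(
      backbone = if (!is.null(backbone))
        lapply(backbone$blocks, function(blk) .conv_block_state(dim(blk$w)[4])),
      texture = if (!is.null(texture))
        lapply(texture$blocks, function(blk) .conv_block_state(dim(blk$w)[4])))
    structure(list(config = cfg, dims = dims,
                   params = list(backbone = backbone, texture = texture, head = head),
                   state = state, class_names = class_names,
                   version = "lbpfuse-checkpoint-1"),
              class = "fusion_model")
  })
}

#' @export
print.fusion_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Dual-branch fusion network (variant: %s)\n", x$config$variant))
  cat(sprintf("  backbone: %s (%s)  rgb dim %d\n", x$config$backbone_name,
              if (is.null(x$params$backbone)) "absent" else "built", d$rgb))
  cat(sprintf("  texture branch: widths %s, SE %s, pool %dx%d -> lbp dim %d\n",
              paste(x$config$lbp_channels, collapse = "-"),
              if (x$config$variant %in% c("no_se", "rgb_only")) "off" else
                sprintf("%d->%d->%d", x$config$lbp_channels[3],
                        x$config$lbp_channels[3] %/% x$config$se_reduction,
                        x$config$lbp_channels[3]),
              x$config$lbp_pool_size, x$config$lbp_pool_size, d$lbp))
  cat(sprintf("  head: %d -> %d classes;  %d parameters\n",
              d$fused, x$config$n_classes, n_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model a `fusion_model`.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_leaves(.trainable(model$params)), length, integer(1)))
}

# Trainable subtree: strip non-numeric metadata (kind, widths, dims, ...)
.trainable <- function(params) {
  keep <- function(p) {
    if (is.list(p)) {
      p <- lapply(p, keep)
      p[!vapply(p, is.null, logical(1))]
    } else if (is.numeric(p) && !is.integer(p)) p else NULL
  }
  keep(params)
}

flatten_leaves <- function(p, prefix = NULL) {
  if (!is.list(p)) {
    out <- list(p); names(out) <- paste(prefix, collapse = "/"); return(out)
  }
  nm <- names(p) %||% as.character(seq_along(p))
  out <- list()
  for (i in seq_along(p))
    out <- c(out, flatten_leaves(p[[i]], c(prefix, nm[i])))
  out
}

#' Differential learning-rate parameter groups
#'
#' Partitions every trainable parameter into exactly two groups — pretrained
#' backbone parameters at `lr_backbone`, newly initialised texture-branch and
#' head parameters at `lr_new` — matching the fine-tuning protocol. For the
#' `lbp_only` variant there is no backbone group and everything trains at
#' `lr_new`.
#'
#' @param model a `fusion_model`.
#' @param lr_backbone backbone learning rate (default 2e-4).
#' @param lr_new texture-branch / head learning rate (default 2e-3).
#' @return named list of groups, each with `paths` (parameter leaf paths) and
#'   `lr`.
#' @export
parameter_groups <- function(model, lr_backbone = 2e-4, lr_new = 2e-3) {
  paths <- names(flatten_leaves(.trainable(model$params)))
  bb <- grepl("^backbone/", paths)
  groups <- list()
  if (any(bb)) groups$backbone <- list(paths = paths[bb], lr = lr_backbone)
  groups$new <- list(paths = paths[!bb], lr = lr_new)
  groups
}

# ---- forward / backward ----------------------------------------------------

.run_blocks_fw <- function(x, blocks, bn_state, train, want_cache,
                           momentum = 0.1, eps = 1e-5, pool = NULL,
                           pool_key = NULL) {
  caches <- vector("list", length(blocks))
  prev <- if (!is.null(pool)) pool[[pool_key]]
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    r <- .conv_block_fw(x, blk$w, blk$b, blk$gamma, blk$beta, train,
                        bn_state[[i]]$mean, bn_state[[i]]$var, eps, want_cache,
                        if (!is.null(prev)) prev[[i]])
    if (train) {
      bn_state[[i]]$mean <- (1 - momentum) * bn_state[[i]]$mean + momentum * r$batch_mean
      bn_state[[i]]$var <- (1 - momentum) * bn_state[[i]]$var + momentum * r$batch_var
    }
    caches[[i]] <- r$cache
    x <- r$out
  }
  if (!is.null(pool)) pool[[pool_key]] <- caches
  list(out = x, caches = caches, bn_state = bn_state)
}

.run_blocks_bw <- function(caches, gout, need_gx_first = FALSE) {
  grads <- vector("list", length(caches))
  g <- gout
  for (i in rev(seq_along(caches))) {
    r <- .conv_block_bw(caches[[i]], g, i > 1 || need_gx_first)
    grads[[i]] <- list(w = r$gw, b = r$gb, gamma = r$ggamma, beta = r$gbeta)
    g <- r$gx
  }
  list(blocks = .name_blocks(grads), gx = g)
}

#' Forward pass of a fusion model
#'
#' @param model a `fusion_model`.
#' @param rgb ImageNet-normalised RGB batch, array (S, S, 3, N); may be
#'   `NULL` for the `lbp_only` variant.
#' @param lbp rescaled-LBP batch in \[0, 1\], array (S, S, 1, N); may be
#'   `NULL` for the `rgb_only` variant.
#' @param train use batch statistics and update running statistics (in the
#'   returned `model`).
#' @param want_cache keep intermediate activations for a backward pass.
#' @return list with `logits` (n_classes x N), `model` (running statistics
#'   possibly updated) and `cache`.
#' @export
fusion_forward <- function(model, rgb = NULL, lbp = NULL, train = FALSE,
                           want_cache = FALSE, pool = NULL) {
  cfg <- model$config
  need_rgb <- cfg$variant != "lbp_only"
  need_lbp <- cfg$variant != "rgb_only"
  if (need_rgb && is.null(rgb))
    stop_invalid("variant '%s' requires the RGB plane", cfg$variant)
  if (need_lbp && is.null(lbp))
    stop_invalid("variant '%s' requires the LBP plane", cfg$variant)
  .check_batch <- function(x, c, what) {
    d <- dim(x)
    if (length(d) != 4 || d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != c)
      stop_invalid("%s batch must have dim (%d, %d, %d, N)", what,
                   cfg$input_size, cfg$input_size, c)
    d[4]
  }
  n <- if (need_rgb) .check_batch(rgb, 3, "rgb") else .check_batch(lbp, 1, "lbp")
  if (need_rgb && need_lbp && dim(lbp)[4] != n)
    stop_invalid("rgb and lbp batches disagree on batch size")

  cache <- list()
  feats <- list()

  if (need_rgb) {
    bb <- model$params$backbone
    x <- .adpool_fw(rgb, bb$input_pool)
    r <- .run_blocks_fw(x, bb$blocks, model$state$backbone, train, want_cache,
                        pool = pool, pool_key = "bb")
    model$state$backbone <- r$bn_state
    pooled <- .adpool_fw(r$out, 1L)
    feats$rgb <- matrix(pooled, bb$feature_dim, n)
    cache$bb <- list(x = if (want_cache) x, caches = r$caches,
                     hook = r$out, hw = dim(r$out)[1:2])
  }
  if (need_lbp) {
    tex <- model$params$texture
    r <- .run_blocks_fw(lbp, tex$blocks, model$state$texture, train, want_cache,
                        pool = pool, pool_key = "tex")
    model$state$texture <- r$bn_state
    if (!is.null(tex$se)) {
      se <- se_fw_batch(r$out, tex$se)
      hook <- se$out
    } else {
      se <- NULL
      hook <- r$out
    }
    pooled <- .adpool_fw(hook, cfg$lbp_pool_size)
    feats$lbp <- matrix(pooled, model$dims$lbp, n)
    cache$tex <- list(caches = r$caches, pre_se = r$out, se = se, hook = hook,
                      hw = dim(hook)[1:2])
  }

  fused <- do.call(rbind, feats[c("rgb", "lbp")[c(need_rgb, need_lbp)]])
  logits <- model$params$head$w %*% fused + model$params$head$b
  cache$fused <- fused
  cache$n <- n
  list(logits = logits, model = model, cache = if (want_cache) cache)
}

# Backward pass: gradient of the loss w.r.t. every trainable parameter.
# `glogits` is n_classes x N. Returns a list mirroring model$params.
fusion_backward <- function(model, cache, glogits) {
  cfg <- model$config
  need_rgb <- cfg$variant != "lbp_only"
  need_lbp <- cfg$variant != "rgb_only"
  grads <- list()
  grads$head <- list(w = glogits %*% t(cache$fused), b = rowSums(glogits))
  gfused <- t(model$params$head$w) %*% glogits
  off <- 0L
  if (need_rgb) {
    bb <- model$params$backbone
    gfeat <- gfused[seq_len(bb$feature_dim), , drop = FALSE]
    off <- bb$feature_dim
    hwd <- dim(cache$bb$hook)
    garr <- array(gfeat, c(1, 1, hwd[3], hwd[4]))
    ghook <- .adpool_bw(garr, hwd[1], hwd[2])
    r <- .run_blocks_bw(cache$bb$caches, ghook, need_gx_first = FALSE)
    grads$backbone <- list(blocks = r$blocks)
  }
  if (need_lbp) {
    tex <- model$params$texture
    gfeat <- gfused[off + seq_len(model$dims$lbp), , drop = FALSE]
    hwd <- dim(cache$tex$hook)
    garr <- array(gfeat, c(cfg$lbp_pool_size, cfg$lbp_pool_size, hwd[3], hwd[4]))
    ghook <- .adpool_bw(garr, hwd[1], hwd[2])
    if (!is.null(tex$se)) {
      r_se <- se_bw_batch(cache$tex$pre_se, cache$tex$se, ghook, tex$se)
      gconv <- r_se$gx
      se_grads <- list(w1 = r_se$gw1, b1 = r_se$gb1, w2 = r_se$gw2, b2 = r_se$gb2)
    } else {
      gconv <- ghook
      se_grads <- NULL
    }
    r <- .run_blocks_bw(cache$tex$caches, gconv, need_gx_first = FALSE)
    grads$texture <- list(blocks = r$blocks, se = se_grads)
  }
  grads
}

#' Softmax probabilities from logits
#' @param logits matrix n_classes x N.
#' @return matrix of the same shape; columns sum to 1.
#' @export
softmax <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# Mean cross-entropy loss and its logit gradient for integer labels (1-based)
cross_entropy <- function(logits, labels) {
  n <- ncol(logits)
  p <- softmax(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, glogits = g / n)
}

# ---- prediction and checkpoints -------------------------------------------

#' Predict classes or probabilities for images
#'
#' Accepts a directory, image paths, or a list of decoded (H, W, 3) arrays in
#' \[0, 255\]. Images are run through the evaluation pipeline (resize only,
#' ImageNet normalisation, per-image LBP plane).
#'
#' @param object a `fusion_model`.
#' @param newdata directory, character vector of paths, or list of arrays.
#' @param type `"prob"` (matrix of class probabilities) or `"class"`.
#' @param batch_size mini-batch size used during inference.
#' @param ... unused.
#' @return probability matrix (images x classes) or factor of class labels.
#' @export
predict.fusion_model <- function(object, newdata, type = c("prob", "class"),
                                 batch_size = 8, ...) {
  type <- match.arg(type)
  imgs <- if (is.character(newdata) && length(newdata) == 1 && dir.exists(newdata)) {
    paths <- list.files(newdata, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    lapply(paths, load_image)
  } else if (is.character(newdata)) {
    lapply(newdata, load_image)
  } else if (is.list(newdata)) newdata else list(newdata)
  probs <- .predict_arrays(object, imgs, batch_size)
  cls <- object$class_names %||% paste0("class", seq_len(object$config$n_classes))
  colnames(probs) <- cls
  if (type == "prob") probs
  else factor(cls[max.col(probs, ties.method = "first")], levels = cls)
}

.predict_arrays <- function(model, imgs, batch_size = 8) {
  s <- model$config$input_size
  n <- length(imgs)
  out <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    duals <- lapply(imgs[idx], function(im) {
      if (any(dim(im)[1:2] != s)) im <- resize_image(im, s)
      prepare_dual(im)
    })
    rgb <- if (model$config$variant != "lbp_only")
      array(unlist(lapply(duals, `[[`, "rgb")), c(s, s, 3, length(idx)))
    lbp <- if (model$config$variant != "rgb_only")
      array(unlist(lapply(duals, `[[`, "lbp")), c(s, s, 1, length(idx)))
    fw <- fusion_forward(model, rgb, lbp, train = FALSE)
    out[idx, ] <- t(softmax(fw$logits))
  }
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialised file holding the versioned parameter
#' map, the architecture configuration, batch-norm running statistics, the
#' class-name list, and any extra metadata.
#'
#' @param model a `fusion_model`.
#' @param path file path.
#' @param extra optional named list stored alongside the model.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `fusion_model` (with attribute `"extra"`).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "fusion_model"))
  saveRDS(list(version = model$version, config = model$config, dims = model$dims,
               params = model$params, state = model$state,
               class_names = model$class_names, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "lbpfuse-checkpoint-1"))
    .config_error("unsupported checkpoint version '%s'", obj$version %||% "<none>")
  model <- structure(list(config = obj$config, dims = obj$dims, params = obj$params,
                          state = obj$state, class_names = obj$class_names,
                          version = obj$version),
                     class = "fusion_model")
  attr(model, "extra") <- obj$extra
  model
}
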