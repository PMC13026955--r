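# YAML run configuration with a strict schema.
#
# Precedence: package defaults < config file < explicit overrides. Unknown
# keys are rejected rather than ignored, so a typo cannot silently change
# the training protocol.

#' Default run configuration
#'
#' The defaults mirror the reference training protocol: batch size 8,
#' 25 epochs, Adam learning rates 0.0002 (backbone) / 0.002 (new layers),
#' cosine annealing with T_max = 25, stratified 70/15/15 split, input size
#' 224, and the standard augmentation recipe.
#'
#' @return nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    data = list(root = NULL, fractions = c(0.70, 0.15, 0.15), seed = 42L,
                batch_size = 8L),
    model = list(n_classes = 5L, variant = "full",
                 backbone = "efficientnetv2_s", pretrained = TRUE,
                 input_size = 224L, lbp_channels = c(16L, 32L, 64L),
                 se_reduction = 16L, lbp_pool_size = 4L),
    train = list(epochs = 25L, lr_backbone = 2e-4, lr_new = 2e-3,
                 t_max = 25L, eta_min = 0, deterministic = TRUE),
    augment = list(hflip_prob = 0.5, max_rotation = 10, jitter = 0.2,
                   enabled = TRUE),
    eval = list(split = "test"),
    paths = list(out = "runs")),
    class = "run_config")
}

.merge_strict <- function(default, new, path = character()) {
  for (key in names(new)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(default))
      .config_error("unknown configuration key '%s'", here)
    dv <- default[[key]]; nv <- new[[key]]
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(nv)) .config_error("key '%s' must be a section", here)
      default[[key]] <- .merge_strict(dv, nv, c(path, key))
    } else {
      if (!is.null(dv) && !is.null(nv)) {
        ok <- (is.numeric(dv) && is.numeric(nv)) ||
          (is.character(dv) && is.character(nv)) ||
          (is.logical(dv) && is.logical(nv))
        if (!ok)
          .config_error("key '%s' has type %s but default is %s", here,
                        class(nv)[1], class(dv)[1])
      }
      default[[key]] <- if (is.integer(dv) && is.numeric(nv)) as.integer(nv) else nv
    }
  }
  default
}

#' Resolve a run configuration
#'
#' Starts from [default_run_config()], merges a YAML file (when given), then
#' merges explicit overrides — increasing precedence. Unknown keys and type
#' mismatches raise a configuration error naming the offending key.
#'
#' @param path optional YAML file.
#' @param overrides optional nested named list (e.g.
#'   `list(train = list(epochs = 2))`).
#' @return resolved `run_config`.
#' @export
#' @examples
#' cfg <- parse_run_config()
#' cfg$train$epochs  # 25
parse_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) .config_error("config file '%s' not found", path)
    cfg <- .merge_strict(cfg, yaml::read_yaml(path))
  }
  cfg <- .merge_strict(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration as YAML
#' @param cfg a `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# model/train/augment sub-objects from a run config
.cfg_model <- function(cfg) {
  fusion_config(n_classes = cfg$model$n_classes, variant = cfg$model$variant,
                backbone_name = cfg$model$backbone,
                pretrained = cfg$model$pretrained,
                lbp_channels = cfg$model$lbp_channels,
                se_reduction = cfg$model$se_reduction,
                lbp_pool_size = cfg$model$lbp_pool_size,
                input_size = cfg$model$input_size)
}

.cfg_train <- function(cfg) {
  train_config(epochs = cfg$train$epochs, batch_size = cfg$data$batch_size,
               lr_backbone = cfg$train$lr_backbone, lr_new = cfg$train$lr_new,
               t_max = cfg$train$t_max, eta_min = cfg$train$eta_min,
               seed = cfg$data$seed, deterministic = cfg$train$deterministic)
}

.cfg_augment <- function(cfg) {
  augmentation_config(size = cfg$model$input_size,
                      hflip_prob = cfg$augment$hflip_prob,
                      max_rotation = cfg$augment$max_rotation,
                      jitter = cfg$augment$jitter, enabled = cfg$augment$enabled)
}
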