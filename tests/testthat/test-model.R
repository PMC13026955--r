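# Dual-branch model assembly and forward/backward contracts

tiny_cfg <- function(variant = "full", ...) {
  fusion_config(variant = variant, backbone_name = "tiny_cnn",
                pretrained = FALSE, ...)
}

rand_batch <- function(n, s = 224, channels = 3) {
  array(rnorm(s * s * channels * n), c(s, s, channels, n))
}

test_that("the default configuration fixes the published feature geometry", {
  d <- fusion_dims(fusion_config())
  expect_equal(d$rgb, 1792)
  expect_equal(d$lbp, 1024)
  expect_equal(d$fused, 2816)
  expect_equal(fusion_dims(fusion_config(variant = "rgb_only"))$fused, 1792)
  expect_equal(fusion_dims(fusion_config(variant = "lbp_only"))$fused, 1024)
  expect_equal(fusion_config()$lbp_channels[3], 64)
})

test_that("the texture branch realises 1024 features via 28x28 maps and SE 64->4->64", {
  model <- build_variant(tiny_cfg("lbp_only"), seed = 1)
  expect_equal(dim(model$params$texture$se$w1), c(4, 64))
  expect_equal(dim(model$params$texture$se$w2), c(64, 4))
  fw <- fusion_forward(model, lbp = rand_batch(2, channels = 1),
                       want_cache = TRUE)
  expect_equal(fw$cache$tex$hw, c(28, 28))           # 224 / 2^3 before pooling
  expect_equal(nrow(fw$cache$fused), 1024)
  expect_equal(ncol(model$params$head$w), 1024)
})

test_that("the backbone contract passes a declared feature dim through", {
  model <- build_variant(tiny_cfg(), seed = 1)
  expect_equal(model$dims$rgb, 32)                   # stand-in declared dim
  fw <- fusion_forward(model, rand_batch(2), rand_batch(2, channels = 1),
                       want_cache = TRUE)
  expect_equal(nrow(fw$cache$fused), 32 + 1024)
  # registry errors
  expect_error(fusion_config(backbone_name = "nope"),
               class = "lbpfuse_config_error")
  expect_error(build_rgb_branch(fusion_config(pretrained = TRUE)),
               class = "lbpfuse_download_required")
  expect_error(build_rgb_branch(fusion_config(pretrained = FALSE)),
               class = "lbpfuse_config_error")
})

test_that("builds are seeded: identical seeds give bit-identical parameters", {
  m1 <- build_variant(tiny_cfg(), seed = 33)
  m2 <- build_variant(tiny_cfg(), seed = 33)
  m3 <- build_variant(tiny_cfg(), seed = 34)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
})

test_that("every variant honours the forward shape contract", {
  for (variant in c("full", "rgb_only", "lbp_only", "no_se")) {
    model <- build_variant(tiny_cfg(variant), seed = 2)
    for (n in c(1, 3)) {
      rgb <- if (variant != "lbp_only") rand_batch(n)
      lbp <- if (variant != "rgb_only") rand_batch(n, channels = 1)
      fw <- fusion_forward(model, rgb, lbp)
      expect_equal(dim(fw$logits), c(5, n))
      expect_equal(colSums(softmax(fw$logits)), rep(1, n), tolerance = 1e-6)
    }
  }
})

test_that("inference is deterministic and missing planes are rejected", {
  model <- build_variant(tiny_cfg(), seed = 4)
  rgb <- rand_batch(2); lbp <- rand_batch(2, channels = 1)
  expect_identical(fusion_forward(model, rgb, lbp)$logits,
                   fusion_forward(model, rgb, lbp)$logits)
  expect_error(fusion_forward(model, rgb, NULL), class = "lbpfuse_invalid_input")
  expect_error(fusion_forward(model, NULL, lbp), class = "lbpfuse_invalid_input")
})

test_that("gradients flow to every trainable parameter in every group", {
  set.seed(11)
  model <- build_variant(tiny_cfg(), seed = 5)
  fw <- fusion_forward(model, rand_batch(2), rand_batch(2, channels = 1),
                       train = TRUE, want_cache = TRUE)
  ce <- lbpfuse:::cross_entropy(fw$logits, c(1L, 3L))
  grads <- lbpfuse:::fusion_backward(model, fw$cache, ce$glogits)
  paths <- names(lbpfuse:::flatten_leaves(lbpfuse:::.trainable(model$params)))
  for (path in paths) {
    g <- lbpfuse:::get_path(grads, path)
    p <- lbpfuse:::get_path(model$params, path)
    expect_false(is.null(g), info = path)
    expect_equal(length(g), length(p), info = path)
    expect_true(all(is.finite(g)), info = path)
  }
})

test_that("parameter groups partition all trainable parameters", {
  model <- build_variant(tiny_cfg(), seed = 6)
  groups <- parameter_groups(model)
  expect_named(groups, c("backbone", "new"))
  expect_equal(groups$backbone$lr, 2e-4)
  expect_equal(groups$new$lr, 2e-3)
  all_paths <- names(lbpfuse:::flatten_leaves(lbpfuse:::.trainable(model$params)))
  expect_setequal(c(groups$backbone$paths, groups$new$paths), all_paths)
  expect_length(intersect(groups$backbone$paths, groups$new$paths), 0)
  # lbp_only: no backbone group, everything trains at the new-layer rate
  g2 <- parameter_groups(build_variant(tiny_cfg("lbp_only"), seed = 6))
  expect_named(g2, "new")
  expect_false(any(grepl("^backbone", g2$new$paths)))
})

test_that("dropping SE removes exactly its parameter count", {
  full <- build_variant(tiny_cfg(), seed = 7)
  nose <- build_variant(tiny_cfg("no_se"), seed = 7)
  expect_lt(n_parameters(nose), n_parameters(full))
  expect_equal(n_parameters(full) - n_parameters(nose),
               64 * 4 + 4 + 4 * 64 + 64)
})

test_that("no_se is the limit of the full model as the SE gate saturates", {
  full <- build_variant(tiny_cfg(), seed = 8)
  nose <- full
  nose$config$variant <- "no_se"
  nose$params$texture$se <- NULL
  full$params$texture$se$w1[] <- 0
  full$params$texture$se$w2[] <- 0
  full$params$texture$se$b2[] <- 50            # sigmoid(50) -> 1
  set.seed(12)
  rgb <- rand_batch(2); lbp <- rand_batch(2, channels = 1)
  expect_equal(fusion_forward(full, rgb, lbp)$logits,
               fusion_forward(nose, rgb, lbp)$logits, tolerance = 1e-4)
})

test_that("checkpoints round-trip the parameter map, config and class names", {
  model <- build_variant(tiny_cfg(), seed = 9,
                         class_names = c("a", "b", "c", "d", "e"))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path, extra = list(epoch = 3L))
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$class_names, model$class_names)
  expect_identical(back$config, model$config)
  expect_equal(attr(back, "extra")$epoch, 3L)
  bad <- readRDS(path); bad$version <- "other"; saveRDS(bad, path)
  expect_error(load_checkpoint(path), class = "lbpfuse_config_error")
})

test_that("predict returns calibrated probabilities and class labels", {
  model <- build_variant(tiny_cfg(), seed = 10,
                         class_names = c("a", "b", "c", "d", "e"))
  set.seed(14)
  imgs <- list(random_rgb_image(224, 224), random_rgb_image(224, 224))
  probs <- predict(model, imgs, type = "prob")
  expect_equal(dim(probs), c(2, 5))
  expect_equal(rowSums(probs), c(1, 1), tolerance = 1e-8)
  cls <- predict(model, imgs, type = "class")
  expect_s3_class(cls, "factor")
  expect_equal(levels(cls), c("a", "b", "c", "d", "e"))
})
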