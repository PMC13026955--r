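# Training engine: schedule, checkpoint selection, smoke runs, determinism

smoke_setup <- function(n_per_class = 8, seed = 1) {
  dir <- file.path(tempdir(), sprintf("train-fix-%d-%d", n_per_class, seed))
  if (!dir.exists(dir)) generate_eye_fixture(dir, n_per_class, size = 224,
                                             seed = seed)
  set <- discover_dataset(dir)
  splits <- stratified_split(set, seed = seed)
  cfg <- fusion_config(backbone_name = "tiny_cnn", pretrained = FALSE)
  list(splits = splits,
       model = build_variant(cfg, seed = seed, class_names = set$class_names))
}

test_that("the cosine schedule matches its closed form", {
  expect_equal(cosine_lr(0.002, 0, 25), 0.002)                # cos(0) = 1
  expect_equal(cosine_lr(0.002, 25, 25), 0)                   # cos(pi) = -1
  expect_equal(cosine_lr(0.002, 5, 25), 0.001 * (1 + cos(0.2 * pi)))
  expect_equal(cosine_lr(0.002, 5, 25), 0.0018090, tolerance = 1e-4)
  expect_equal(cosine_lr(0.1, 3, 10, eta_min = 0.01),
               0.01 + 0.5 * 0.09 * (1 + cos(0.3 * pi)))
  expect_error(cosine_lr(0.002, -1, 25), class = "lbpfuse_invalid_input")
  expect_error(cosine_lr(0.002, 26, 25), class = "lbpfuse_invalid_input")
})

test_that("checkpoint selection maximises validation accuracy, earliest tie", {
  expect_equal(select_checkpoint(c(0.5, 0.9, 0.7)), 2)
  expect_equal(select_checkpoint(c(0.8, 0.8)), 1)
  expect_equal(select_checkpoint(0.3), 1)
  expect_equal(select_checkpoint(data.frame(val_acc = c(0.1, 0.4, 0.4))), 2)
  expect_error(select_checkpoint(numeric(0)), class = "lbpfuse_invalid_input")
})

test_that("a short run produces complete logs with the scheduled rates", {
  s <- smoke_setup()
  res <- train_model(s$model, s$splits, train_config(epochs = 2, seed = 3))
  expect_s3_class(res, "train_result")
  expect_equal(nrow(res$logs), 2)
  expect_true(all(is.finite(res$logs$train_loss)))
  expect_true(all(res$logs$train_loss >= 0))
  expect_true(all(res$logs$val_acc >= 0 & res$logs$val_acc <= 1))
  # logged rates equal the closed form for both groups, every epoch
  for (e in 1:2) {
    expect_equal(res$logs$lr_backbone[e], cosine_lr(2e-4, e - 1, 25))
    expect_equal(res$logs$lr_new[e], cosine_lr(2e-3, e - 1, 25))
  }
  # proportional decay: the group ratio is constant at 0.1
  expect_equal(res$logs$lr_backbone / res$logs$lr_new, rep(0.1, 2),
               tolerance = 1e-12)
  expect_equal(res$best_epoch, select_checkpoint(res$logs))
})

test_that("training is bit-reproducible under a fixed seed", {
  s <- smoke_setup(seed = 2)
  cfg <- train_config(epochs = 2, seed = 11, deterministic = TRUE)
  r1 <- train_model(s$model, s$splits, cfg)
  r2 <- train_model(s$model, s$splits, cfg)
  expect_identical(r1$logs, r2$logs)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("degenerate inputs are rejected with informative errors", {
  s <- smoke_setup(seed = 3)
  empty <- s$splits
  empty$train$items <- empty$train$items[0, ]
  expect_error(train_model(s$model, empty, train_config(epochs = 1)),
               class = "lbpfuse_config_error")
  expect_error(train_config(epochs = 0), class = "lbpfuse_config_error")
  expect_error(train_config(lr_new = 0), class = "lbpfuse_config_error")
})

test_that("the full protocol overfits the fixture (3-seed majority)", {
  b <- e2e_bundle()
  final_train <- vapply(b$full, function(r) tail(r$logs$train_acc, 1), numeric(1))
  expect_gte(sum(final_train >= 0.95), 2)            # majority of 3 seeds
})

test_that("training reduces the loss from first to last epoch (3-seed median)", {
  b <- e2e_bundle()
  drop <- vapply(b$full, function(r)
    r$logs$train_loss[1] - tail(r$logs$train_loss, 1), numeric(1))
  expect_gt(median(drop), 0)
})
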