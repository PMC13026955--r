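# Shared end-to-end training bundle, computed once per test session and
# reused by the training, explainability and acceptance tests. Study
# conditions: 40 images/class synthetic fixture at 224 px, batch 8, the full
# 25-epoch protocol for the full and no_se variants over seeds 1..3 / seed 1,
# and a shorter 10-epoch budget for the lbp_only chance-accuracy check.

.e2e_env <- new.env(parent = emptyenv())

e2e_bundle <- function() {
  if (!is.null(.e2e_env$bundle)) return(.e2e_env$bundle)

  dir <- file.path(tempdir(), "lbpfuse-e2e-fixture")
  gen <- generate_eye_fixture(dir, n_per_class = 40, size = 224, seed = 42,
                              lesion_masks = TRUE)
  set <- discover_dataset(dir)
  splits <- stratified_split(set, seed = 42)
  images <- list(train = lbpfuse:::load_dataset(splits$train),
                 val = lbpfuse:::load_dataset(splits$val))
  test_images <- lbpfuse:::load_dataset(splits$test)

  run_variant <- function(variant, seed, epochs) {
    cfg <- fusion_config(variant = variant, backbone_name = "tiny_cnn",
                         pretrained = FALSE)
    model <- build_variant(cfg, seed = seed, class_names = set$class_names)
    res <- train_model(model, splits, train_config(epochs = epochs, seed = seed),
                       images = images)
    ev <- evaluate_model(res$model, splits$test, images = test_images)
    list(logs = res$logs, best_epoch = res$best_epoch,
         test_acc = ev$report$accuracy, model = res$model)
  }

  full <- lapply(1:3, function(s) run_variant("full", s, 25))
  lbp_only <- lapply(1:3, function(s) run_variant("lbp_only", s, 10))
  no_se <- run_variant("no_se", 1, 25)

  .e2e_env$bundle <- list(
    dir = dir, set = set, splits = splits, masks = gen$masks,
    manifest = gen$manifest, test_images = test_images,
    full = full, lbp_only = lbp_only, no_se = no_se)
  .e2e_env$bundle
}
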