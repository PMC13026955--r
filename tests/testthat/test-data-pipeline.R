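# Dataset discovery, stratified splitting, augmentation and dual samples

make_toy_set <- function(sizes) {
  # labeled set with fake paths; splitting never touches the files
  items <- do.call(rbind, lapply(seq_along(sizes), function(i)
    data.frame(path = sprintf("c%d_%03d.png", i, seq_len(sizes[i])),
               class = i - 1L, class_name = paste0("c", i),
               stringsAsFactors = FALSE)))
  structure(list(items = items, class_names = paste0("c", seq_along(sizes))),
            class = "labeled_image_set")
}

test_that("discovery orders classes and files lexicographically", {
  dir <- file.path(tempdir(), "disc-fixture")
  unlink(dir, recursive = TRUE)
  generate_eye_fixture(dir, n_per_class = 3, size = 64, seed = 1)
  set <- discover_dataset(dir)
  expect_equal(nrow(set$items), 15)
  expect_equal(set$class_names,
               c("cataract", "conjunctivitis", "eyelid", "normal", "uveitis"))
  expect_equal(set$items$class[1:3], rep(0L, 3))
  expect_false(is.unsorted(set$items$path[set$items$class == 0L]))
})

test_that("discovery rejects degenerate trees and skips unreadable files", {
  root <- file.path(tempdir(), "disc-bad"); unlink(root, recursive = TRUE)
  dir.create(file.path(root, "only"), recursive = TRUE)
  png::writePNG(matrix(0.5, 4, 4), file.path(root, "only", "a.png"))
  expect_error(discover_dataset(root), class = "lbpfuse_dataset_error")

  dir.create(file.path(root, "empty"))
  expect_error(discover_dataset(root), class = "lbpfuse_dataset_error")

  writeLines("not an image", file.path(root, "empty", "fake.png"))
  png::writePNG(matrix(0.5, 4, 4), file.path(root, "empty", "real.png"))
  expect_warning(set <- discover_dataset(root), "unreadable")
  expect_equal(nrow(set$items), 2)
})

test_that("stratified split allocates by per-class largest remainder", {
  set <- make_toy_set(c(60, 40))
  sp <- stratified_split(set, seed = 1)
  expect_equal(nrow(sp$train$items), 70)             # 42 + 28
  expect_equal(sum(sp$train$items$class == 0), 42)
  expect_equal(sum(sp$train$items$class == 1), 28)
  # disjoint partition recovering the input
  all_paths <- sort(c(sp$train$items$path, sp$val$items$path, sp$test$items$path))
  expect_equal(all_paths, sort(set$items$path))
  expect_length(intersect(sp$train$items$path, sp$test$items$path), 0)
})

test_that("splits are seeded and per-class fractions stay within one item", {
  set <- make_toy_set(c(17, 23, 9, 40))
  a <- stratified_split(set, seed = 7)
  b <- stratified_split(set, seed = 7)
  c <- stratified_split(set, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$train$items$path, c$train$items$path))
  for (ci in 0:3) {
    n <- sum(set$items$class == ci)
    expect_lt(abs(sum(a$test$items$class == ci) - 0.15 * n), 1)
  }
  expect_error(stratified_split(make_toy_set(c(10, 2))),
               class = "lbpfuse_stratification_error")
  expect_error(stratified_split(set, fractions = c(0.5, 0.2, 0.2)),
               class = "lbpfuse_dataset_error")
})

test_that("the split manifest records every item once", {
  set <- make_toy_set(c(10, 10))
  sp <- stratified_split(set, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_split_manifest(sp, path)
  man <- read.csv(path)
  expect_equal(nrow(man), 20)
  expect_setequal(unique(man$split), c("train", "val", "test"))
  expect_setequal(man$path, set$items$path)
})

test_that("augmentation resizes to 224 and is the identity when disabled", {
  set.seed(21)
  img <- random_rgb_image(100, 80)
  out <- augment_image(img, augmentation_config(enabled = FALSE))
  expect_equal(dim(out), c(224, 224, 3))
  expect_equal(out, resize_image(img, 224))
  out2 <- augment_image(img)
  expect_equal(dim(out2), c(224, 224, 3))
  expect_true(all(out2 >= 0 & out2 <= 255))
})

test_that("augmentation streams are reproducible under a fixed seed", {
  img <- random_rgb_image(64, 64)
  cfg <- augmentation_config(size = 64)
  set.seed(99); a <- augment_image(img, cfg)
  set.seed(99); b <- augment_image(img, cfg)
  set.seed(100); c <- augment_image(img, cfg)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("dual samples carry ImageNet-normalised RGB and a [0,1] LBP plane", {
  img <- array(128, c(32, 32, 3))
  d <- prepare_dual(img)
  expect_equal(dim(d$rgb), c(32, 32, 3))
  expect_equal(dim(d$lbp), c(32, 32, 1))
  means <- c(0.485, 0.456, 0.406); stds <- c(0.229, 0.224, 0.225)
  for (c in 1:3)
    expect_equal(d$rgb[1, 1, c], (128 / 255 - means[c]) / stds[c],
                 tolerance = 1e-12)
  expect_equal(d$rgb[1, 1, 1], 0.0741, tolerance = 1e-3)
  expect_true(all(d$lbp >= 0 & d$lbp <= 1))
  # constant image -> constant texture plane
  expect_equal(length(unique(as.vector(d$lbp))), 1)
  set.seed(31)
  d2 <- prepare_dual(random_rgb_image())
  expect_true(all(d2$lbp >= 0 & d2$lbp <= 1))
})
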