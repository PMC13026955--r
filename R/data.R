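# Folder-per-class dataset discovery, seeded stratified splitting, the
# augmentation + normalisation recipe, and construction of spatially aligned
# RGB + LBP sample pairs.

.IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
.IMAGENET_STD <- c(0.229, 0.224, 0.225)

.dataset_error <- function(fmt, ...) {
  stop(structure(class = c("lbpfuse_dataset_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# cheap validity probe: PNG or JPEG magic bytes
.readable_image <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (length(magic) < 3) return(FALSE)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47))
  jpg_sig <- as.raw(c(0xff, 0xd8, 0xff))
  identical(magic[1:4], png_sig) || identical(magic[1:3], jpg_sig)
}

#' Discover a folder-per-class image dataset
#'
#' Each subdirectory of `root` is one class; class names are the folder names
#' in lexicographic order (so for the five-class ocular layout the indices
#' are cataract < conjunctivitis < eyelid < normal < uveitis). Files are
#' ordered lexicographically within a class. Files whose header is not a
#' valid PNG/JPEG signature are skipped with a warning.
#'
#' @param root dataset directory.
#' @return object of class `labeled_image_set`: list with `items` (data frame
#'   of `path`, `class` — 0-based class index — and `class_name`) and
#'   `class_names`.
#' @export
discover_dataset <- function(root) {
  if (!dir.exists(root)) .dataset_error("dataset root '%s' does not exist", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  if (length(dirs) < 2)
    .dataset_error("dataset root '%s' must contain at least 2 class folders, found %d",
                   root, length(dirs))
  class_names <- basename(dirs)
  items <- lapply(seq_along(dirs), function(i) {
    files <- sort(list.files(dirs[i], pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
    ok <- vapply(files, .readable_image, logical(1))
    if (any(!ok))
      warning(sprintf("skipping %d unreadable image file(s) in class '%s': %s",
                      sum(!ok), class_names[i],
                      paste(basename(files[!ok]), collapse = ", ")),
              call. = FALSE)
    files <- files[ok]
    if (length(files) == 0)
      .dataset_error("class folder '%s' contains no readable JPEG/PNG images",
                     class_names[i])
    data.frame(path = files, class = i - 1L, class_name = class_names[i],
               stringsAsFactors = FALSE)
  })
  structure(list(items = do.call(rbind, items), class_names = class_names),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled image set: %d images, %d classes\n",
              nrow(x$items), length(x$class_names)))
  print(table(factor(x$items$class_name, levels = x$class_names)))
  invisible(x)
}

.subset_lis <- function(set, idx) {
  structure(list(items = set$items[idx, , drop = FALSE],
                 class_names = set$class_names),
            class = "labeled_image_set")
}

#' Seeded stratified train/validation/test split
#'
#' Within each class, items are shuffled by a seeded generator and allocated
#' to the three fractions by largest-remainder rounding (ties resolved in
#' train > validation > test priority), so every class contributes to each
#' subset in proportion — each per-class count is within one item of the
#' exact fraction. The same seed always reproduces the same split.
#'
#' @param set a `labeled_image_set`; every class must have at least 3 items.
#' @param fractions train/validation/test fractions, positive, summing to 1
#'   (default 0.70 / 0.15 / 0.15).
#' @param seed integer seed.
#' @return named list of three disjoint `labeled_image_set`s (`train`,
#'   `val`, `test`) whose union is the input.
#' @export
stratified_split <- function(set, fractions = c(0.70, 0.15, 0.15), seed = 42L) {
  stopifnot(inherits(set, "labeled_image_set"))
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    .dataset_error("fractions must be three positive values summing to 1")
  counts <- table(factor(set$items$class, levels = seq_along(set$class_names) - 1L))
  if (any(counts < 3))
    stop(structure(class = c("lbpfuse_stratification_error", "error", "condition"),
                   list(message = sprintf(
                     "every class needs at least 3 items to stratify; offender(s): %s",
                     paste(set$class_names[counts < 3], collapse = ", ")),
                     call = sys.call())))
  assign_split <- function(n) {
    exact <- n * fractions
    base <- floor(exact)
    short <- n - sum(base)
    if (short > 0) {
      # largest remainder; ties broken by (train, val, test) priority order
      pri <- order(-(exact - base), seq_along(fractions))[seq_len(short)]
      base[pri] <- base[pri] + 1
    }
    rep(c("train", "val", "test"), times = base)
  }
  lab <- character(nrow(set$items))
  with_seed(seed, {
    for (ci in seq_along(set$class_names) - 1L) {
      idx <- which(set$items$class == ci)
      idx <- idx[sample.int(length(idx))]
      lab[idx] <- assign_split(length(idx))
    }
  })
  list(train = .subset_lis(set, lab == "train"),
       val = .subset_lis(set, lab == "val"),
       test = .subset_lis(set, lab == "test"))
}

#' Write a split manifest CSV
#'
#' Records `(path, class, split)` for every item so a run can be audited and
#' reproduced.
#'
#' @param splits result of [stratified_split()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(splits, path) {
  df <- do.call(rbind, lapply(names(splits), function(s) {
    it <- splits[[s]]$items
    data.frame(path = it$path, class = it$class_name,
               split = rep(s, nrow(it)), stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load an 8-bit image as an (H, W, 3) array in \[0, 255\]
#'
#' Grayscale images are expanded to three equal planes; any alpha plane is
#' dropped.
#'
#' @param path PNG or JPEG file.
#' @return numeric array (H, W, 3).
#' @export
load_image <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  dat <- EBImage::imageData(img)
  if (length(d) == 2) dat <- array(rep(dat, 3), c(d[1], d[2], 3))
  if (dim(dat)[3] > 3) dat <- dat[, , 1:3, drop = FALSE]
  aperm(dat, c(2, 1, 3)) * 255
}

#' Bilinear resize of an (H, W, 3) array
#' @param img numeric array (H, W, 3) in \[0, 255\].
#' @param size target square size in pixels.
#' @return resized array (size, size, 3).
#' @export
resize_image <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  ebi <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::resize(ebi, w = size, h = size, filter = "bilinear")
  pmin(pmax(aperm(EBImage::imageData(out), c(2, 1, 3)) * 255, 0), 255)
}

#' Augmentation configuration
#'
#' The training recipe: resize to `size`, random horizontal flip, random
#' rotation within `max_rotation` degrees (bilinear, zero fill), and colour
#' jitter scaling brightness/contrast/saturation by factors drawn from
#' U(1 - jitter, 1 + jitter). With `enabled = FALSE` (evaluation mode) only
#' the resize is applied.
#'
#' @param size output size in pixels (default 224).
#' @param hflip_prob horizontal flip probability (default 0.5).
#' @param max_rotation rotation limit in degrees (default 10).
#' @param jitter jitter fraction (default 0.2).
#' @param enabled apply the random transforms.
#' @return list of class `augmentation_config`.
#' @export
augmentation_config <- function(size = 224, hflip_prob = 0.5, max_rotation = 10,
                                jitter = 0.2, enabled = TRUE) {
  if (hflip_prob < 0 || hflip_prob > 1) stop_invalid("hflip_prob must be in [0, 1]")
  if (max_rotation < 0) stop_invalid("max_rotation must be >= 0")
  structure(list(size = size, hflip_prob = hflip_prob,
                 max_rotation = max_rotation, jitter = jitter, enabled = enabled),
            class = "augmentation_config")
}

#' Apply the augmentation recipe to one RGB image
#'
#' Order: resize, random horizontal flip, random rotation (bilinear, zero
#' fill outside), colour jitter (brightness scale, contrast blend about the
#' grayscale mean, saturation blend against the per-pixel grayscale).
#' Consumes randomness from the current RNG stream; seed the session for
#' reproducible streams.
#'
#' @param img decoded RGB array (H, W, 3) in \[0, 255\].
#' @param cfg an `augmentation_config`.
#' @return augmented array (size, size, 3) in \[0, 255\].
#' @export
augment_image <- function(img, cfg = augmentation_config()) {
  img <- resize_image(img, cfg$size)
  if (!cfg$enabled) return(img)
  flip <- runif(1) < cfg$hflip_prob
  angle <- runif(1, -cfg$max_rotation, cfg$max_rotation)
  f <- runif(3, 1 - cfg$jitter, 1 + cfg$jitter)
  .augment_warp(img, flip, angle, f[1], f[2], f[3])
}

#' Build the aligned RGB + LBP sample pair for one image
#'
#' The RGB plane is scaled to \[0, 1\] and standardised with the ImageNet
#' statistics (mean 0.485/0.456/0.406, sd 0.229/0.224/0.225). The texture
#' plane is the rescaled uniform-LBP code image of the grayscale conversion,
#' divided by 255 into \[0, 1\]. Both derive from the same (post-augmentation)
#' image, so the two branches always see corresponding geometry.
#'
#' @param img RGB array (H, W, 3) in \[0, 255\].
#' @return list with `rgb` (H, W, 3) and `lbp` (H, W, 1).
#' @export
prepare_dual <- function(img) {
  d <- dim(img)
  rgb <- img / 255
  for (c in 1:3) rgb[, , c] <- (rgb[, , c] - .IMAGENET_MEAN[c]) / .IMAGENET_STD[c]
  lbp <- rescale_codes(lbp_transform(to_grayscale(img))) / 255
  list(rgb = rgb, lbp = array(lbp, c(d[1], d[2], 1)))
}

# Load every image of a labeled set into memory (decoded, original size).
load_dataset <- function(set) {
  lapply(set$items$path, load_image)
}
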