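# Seeded synthetic ocular-style fixture datasets.
#
# Five classes whose signatures mirror the phenotypes of the clinical
# problem and are separable jointly by colour and texture, so that both the
# RGB and the texture branch carry discriminative signal:
#   normal          clean eye composition, low noise
#   cataract        central Gaussian haze over the lens (whitened + smoothed)
#   conjunctivitis  elevated red channel in the sclera
#   uveitis         the SAME elevated redness plus high-frequency speckle,
#                   so colour alone cannot separate it from conjunctivitis
#   eyelid          dark occluding band with a wavy edge over the top third
# Every image adds Gaussian pixel noise and jitters the eye geometry; the
# whole tree is a deterministic function of the seed.

.fixture_classes <- c("cataract", "conjunctivitis", "eyelid", "normal", "uveitis")

# 3x3 box filter with replicate borders
.box3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1, 1:h, h), c(1, 1:w, w)]
  acc <- matrix(0, h, w)
  for (dy in 0:2) for (dx in 0:2)
    acc <- acc + p[(1 + dy):(h + dy), (1 + dx):(w + dx)]
  acc / 9
}

.render_eye <- function(size, class) {
  cy <- size / 2 + runif(1, -0.03, 0.03) * size
  cx <- size / 2 + runif(1, -0.03, 0.03) * size
  r <- 0.18 * size * runif(1, 0.9, 1.1)
  ax <- 0.42 * size; ay <- 0.28 * size
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  sclera <- ((yy - cy) / ay)^2 + ((xx - cx) / ax)^2 <= 1
  d2 <- (yy - cy)^2 + (xx - cx)^2
  iris <- d2 <= r^2
  pupil <- d2 <= (0.45 * r)^2

  skin <- c(205, 170, 150) * runif(1, 0.95, 1.05)
  iris_col <- c(110, 80, 60) * runif(1, 0.85, 1.15)
  img <- array(0, c(size, size, 3))
  for (c in 1:3) {
    plane <- matrix(skin[c], size, size) + (yy - size / 2) * 0.05
    plane[sclera] <- c(248, 243, 238)[c]
    plane[iris] <- iris_col[c]
    plane[pupil] <- c(25, 20, 20)[c]
    img[, , c] <- plane
  }

  lesion <- matrix(FALSE, size, size)
  if (class %in% c("conjunctivitis", "uveitis")) {
    red <- sclera & !iris
    img[, , 1][red] <- img[, , 1][red] + 75
    img[, , 2][red] <- img[, , 2][red] - 25
    img[, , 3][red] <- img[, , 3][red] - 20
    lesion <- red
  }
  if (class == "uveitis") {
    # granular speckle: 3x3-smoothed noise, so neighbouring pixels correlate
    # and the sign patterns differ from those of flat regions under iid
    # sensor noise (plain iid speckle is invisible to LBP, whose codes only
    # see signs, not amplitudes)
    speckle <- .box3(matrix(rnorm(size^2, 0, 45), size, size))
    for (c in 1:3) img[, , c][sclera] <- img[, , c][sclera] + speckle[sclera]
    lesion <- sclera & !iris
  }
  if (class == "cataract") {
    haze <- exp(-d2 / (2 * (0.8 * r)^2)) * 0.85
    for (c in 1:3)
      img[, , c] <- img[, , c] * (1 - haze) + 235 * haze
    lesion <- d2 <= (0.8 * r)^2
  }
  if (class == "eyelid") {
    edge <- round(size * 0.33 + 0.04 * size *
                    sin(seq_len(size) / size * 2 * pi * runif(1, 1.5, 3)))
    band <- yy <= matrix(edge, size, size, byrow = TRUE)
    for (c in 1:3) img[, , c][band] <- c(120, 90, 75)[c] * runif(1, 0.9, 1.1)
    lesion <- band
  }

  img <- img + array(rnorm(3 * size^2, 0, 3), c(size, size, 3))
  list(img = pmin(pmax(img, 0), 255), lesion = lesion,
       geom = list(cy = cy, cx = cx, r = r))
}

#' Generate a seeded synthetic five-class ocular fixture dataset
#'
#' Writes a folder-per-class tree of lossless PNGs (classes: cataract,
#' conjunctivitis, eyelid, normal, uveitis). The output is fully determined
#' by the seed — the same seed reproduces bit-identical files — and always
#' satisfies the preconditions of [discover_dataset()] and
#' [stratified_split()] for `n_per_class >= 3`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_class images per class (default 40).
#' @param size square image size in pixels (default 224).
#' @param seed integer seed.
#' @param lesion_masks also return per-image lesion masks (in memory; useful
#'   for localisation checks).
#' @return invisibly, a list with `manifest` (data frame of path and class)
#'   and, when requested, `masks` (list of logical matrices parallel to the
#'   manifest; `NULL` entries for images without a lesion region).
#' @export
generate_eye_fixture <- function(out_dir, n_per_class = 40, size = 224,
                                 seed = 42L, lesion_masks = FALSE) {
  if (n_per_class < 3)
    stop_invalid("n_per_class must be >= 3 so every class can be stratified")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok)
    stop(structure(class = c("lbpfuse_io_error", "error", "condition"),
                   list(message = sprintf("cannot create directory '%s'", out_dir),
                        call = sys.call())))
  rows <- list(); masks <- list()
  with_seed(seed, {
    for (cls in .fixture_classes) {
      dir.create(file.path(out_dir, cls), showWarnings = FALSE)
      for (i in seq_len(n_per_class)) {
        sc <- .render_eye(size, cls)
        path <- file.path(out_dir, cls, sprintf("%s_%03d.png", cls, i))
        png::writePNG(sc$img / 255, path)
        rows[[length(rows) + 1]] <- data.frame(path = path, class = cls,
                                               stringsAsFactors = FALSE)
        if (lesion_masks)
          masks[length(masks) + 1] <- list(if (any(sc$lesion)) sc$lesion)
      }
    }
  })
  invisible(list(manifest = do.call(rbind, rows),
                 masks = if (lesion_masks) masks))
}

.chi2_dist <- function(a, b) {
  s <- a + b
  ok <- s > 0
  0.5 * sum((a[ok] - b[ok])^2 / s[ok])
}

.lbp_hist <- function(img) {
  codes <- lbp_transform(to_grayscale(img))
  tabulate(codes + 1L, nbins = 59) / length(codes)
}

#' Texture separability report of a dataset
#'
#' Computes the per-class mean 59-bin uniform-LBP histograms and reports
#' chi-square distances between class means for all unordered class pairs,
#' together with the mean within-class distance (images to their own class
#' mean). Classes whose between-class distance exceeds the within-class
#' spread are separable on texture alone.
#'
#' @param dataset a dataset directory or a `labeled_image_set`.
#' @return object of class `texture_separability`: list with `between`
#'   (distance matrix between class means), `within` (named vector),
#'   `pairs` (data frame of all unordered pairs), `class_names`.
#' @export
texture_separability <- function(dataset) {
  set <- if (inherits(dataset, "labeled_image_set")) dataset
  else discover_dataset(dataset)
  k <- length(set$class_names)
  hists <- lapply(set$items$path, function(p) .lbp_hist(load_image(p)))
  cls <- set$items$class
  means <- lapply(0:(k - 1), function(ci)
    Reduce(`+`, hists[cls == ci]) / sum(cls == ci))
  between <- matrix(0, k, k, dimnames = list(set$class_names, set$class_names))
  for (i in 1:k) for (j in 1:k)
    between[i, j] <- .chi2_dist(means[[i]], means[[j]])
  within <- vapply(0:(k - 1), function(ci)
    mean(vapply(hists[cls == ci], .chi2_dist, numeric(1), b = means[[ci + 1]])),
    numeric(1))
  names(within) <- set$class_names
  idx <- which(upper.tri(between), arr.ind = TRUE)
  pairs <- data.frame(class_a = set$class_names[idx[, 1]],
                      class_b = set$class_names[idx[, 2]],
                      distance = between[idx], stringsAsFactors = FALSE)
  structure(list(between = between, within = within, pairs = pairs,
                 class_names = set$class_names),
            class = "texture_separability")
}

#' @export
print.texture_separability <- function(x, ...) {
  cat("texture separability (chi-square distance of mean LBP histograms)\n")
  cat(sprintf("mean within-class distance: %.4f\n", mean(x$within)))
  print(x$pairs[order(-x$pairs$distance), ], row.names = FALSE)
  invisible(x)
}
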