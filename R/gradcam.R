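# Grad-CAM explainability for the two branches.
#
# Hook layers: RGB branch — the backbone's last feature stage before global
# average pooling; texture branch — the third convolutional block's output
# after the SE gate. Channel weights are the spatially averaged gradients of
# the target-class logit w.r.t. the hooked activations; the map is the ReLU
# of the weighted activation sum, bilinearly upsampled to the input size and
# min-max normalised (an all-constant raw map becomes all zeros).

# Bilinear upsampling of a matrix to (H, W) (half-pixel centre alignment).
bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  sy <- pmin(pmax((seq_len(H) - 0.5) * h / H - 0.5, 0), h - 1)
  sx <- pmin(pmax((seq_len(W) - 0.5) * w / W - 0.5, 0), w - 1)
  y0 <- pmin(floor(sy), h - 1); y1 <- pmin(y0 + 1, h - 1); fy <- sy - y0
  x0 <- pmin(floor(sx), w - 1); x1 <- pmin(x0 + 1, w - 1); fx <- sx - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  a
}

#' Grad-CAM activation map for one branch
#'
#' @param model a `fusion_model` whose variant contains the requested branch.
#' @param sample a dual sample as returned by [prepare_dual()] (list with
#'   `rgb` and/or `lbp` planes).
#' @param branch `"rgb"` or `"lbp"`.
#' @param target_class 0-based class index the map explains.
#' @return object of class `activation_map`: list with `map` (input-size
#'   matrix in \[0, 1\]), `branch`, `target_class`.
#' @export
grad_cam <- function(model, sample, branch = c("rgb", "lbp"), target_class) {
  branch <- match.arg(branch)
  cfg <- model$config
  if (branch == "rgb" && cfg$variant == "lbp_only")
    .config_error("variant 'lbp_only' has no RGB branch to explain")
  if (branch == "lbp" && cfg$variant == "rgb_only")
    .config_error("variant 'rgb_only' has no texture branch to explain")
  if (target_class < 0 || target_class >= cfg$n_classes)
    stop_invalid("target_class must lie in [0, %d)", cfg$n_classes)
  s <- cfg$input_size
  rgb <- if (cfg$variant != "lbp_only") array(sample$rgb, c(s, s, 3, 1))
  lbp <- if (cfg$variant != "rgb_only") array(sample$lbp, c(s, s, 1, 1))
  fw <- fusion_forward(model, rgb, lbp, train = FALSE, want_cache = TRUE)
  cache <- fw$cache

  # gradient of the target logit w.r.t. the fused feature vector is the
  # corresponding row of the head weights
  gfused <- model$params$head$w[target_class + 1L, ]
  rgb_dim <- if (cfg$variant == "lbp_only") 0L else model$dims$rgb

  if (branch == "rgb") {
    A <- cache$bb$hook                      # (h, w, C, 1)
    gfeat <- gfused[seq_len(rgb_dim)]
    hwd <- dim(A)
    ghook <- .adpool_bw(array(gfeat, c(1, 1, hwd[3], 1)), hwd[1], hwd[2])
  } else {
    A <- cache$tex$hook                     # post-SE (h, w, C, 1)
    gfeat <- gfused[rgb_dim + seq_len(model$dims$lbp)]
    hwd <- dim(A)
    ghook <- .adpool_bw(array(gfeat, c(cfg$lbp_pool_size, cfg$lbp_pool_size,
                                       hwd[3], 1)), hwd[1], hwd[2])
  }
  hw <- hwd[1] * hwd[2]
  alpha <- colMeans(matrix(ghook, hw, hwd[3]))          # spatially averaged grads
  raw <- matrix(matrix(A, hw, hwd[3]) %*% alpha, hwd[1], hwd[2])
  raw <- pmax(raw, 0)
  up <- bilinear_upsample(raw, s, s)
  rng <- range(up)
  map <- if (rng[2] - rng[1] < 1e-12) matrix(0, s, s)
  else (up - rng[1]) / (rng[2] - rng[1])
  structure(list(map = map, branch = branch, target_class = as.integer(target_class)),
            class = "activation_map")
}

# simple blue -> red heat colormap on [0, 1]; returns (H, W, 3) in [0, 255]
.heat_colors <- function(map) {
  r <- pmin(pmax(1.5 - abs(4 * map - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * map - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * map - 1), 0), 1)
  array(c(r, g, b), c(dim(map), 3)) * 255
}

#' Overlay an activation map on an image
#'
#' Alpha-blends a colorised heatmap over the RGB image:
#' `out = (1 - alpha) * image + alpha * heat`.
#'
#' @param map an `activation_map` (or a matrix in \[0, 1\]).
#' @param image RGB array (H, W, 3) in \[0, 255\] with matching dims.
#' @param alpha blend weight of the heat layer (default 0.4).
#' @return blended RGB array (H, W, 3) in \[0, 255\].
#' @export
overlay_cam <- function(map, image, alpha = 0.4) {
  m <- if (inherits(map, "activation_map")) map$map else map
  if (!all(dim(m) == dim(image)[1:2]))
    stop_invalid("activation map dims (%s) do not match image dims (%s)",
                 paste(dim(m), collapse = "x"),
                 paste(dim(image)[1:2], collapse = "x"))
  (1 - alpha) * image + alpha * .heat_colors(m)
}
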