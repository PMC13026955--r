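# Squeeze-and-excitation channel attention.
#
# squeeze: global average pooling of each channel to a scalar
#   z_c = (1 / (H W)) sum_ij x_c(i, j)
# excite: bottleneck MLP with sigmoid gate
#   s = sigmoid(W2 relu(W1 z + b1) + b2),  W1: (C/r) x C,  W2: C x (C/r)
# apply:  out_c = s_c * x_c (broadcast over space)
#
# Both fully connected layers carry bias terms (standard SE practice);
# biases initialise to zero so a zero-weight block gates every channel at
# exactly sigmoid(0) = 0.5.

#' Initialise squeeze-and-excitation parameters
#'
#' Weights are drawn from a uniform fan-in scheme (U(-sqrt(1/fan_in),
#' sqrt(1/fan_in))), biases start at zero. The reduction ratio must divide the
#' channel count.
#'
#' @param channels number of feature channels C.
#' @param reduction bottleneck reduction ratio r (default 16, giving a hidden
#'   width of C / r; the texture branch uses C = 64, r = 16, hidden width 4).
#' @param seed optional integer seed for reproducible initialisation.
#' @return list of class `se_params` with `w1` ((C/r) x C), `b1`, `w2`
#'   (C x (C/r)), `b2`, `channels`, `reduction`.
#' @export
se_params <- function(channels, reduction = 16, seed = NULL) {
  if (channels %% reduction != 0)
    stop_invalid("reduction %d must divide the channel count %d", reduction, channels)
  hidden <- channels %/% reduction
  draw <- function() {
    b1 <- sqrt(1 / channels); b2 <- sqrt(1 / hidden)
    list(w1 = matrix(runif(hidden * channels, -b1, b1), hidden, channels),
         b1 = numeric(hidden),
         w2 = matrix(runif(channels * hidden, -b2, b2), channels, hidden),
         b2 = numeric(channels),
         channels = channels, reduction = reduction)
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(p, class = "se_params")
}

#' Squeeze: global average pooling per channel
#'
#' @param x numeric array of dim (H, W, C), a single-sample feature map with
#'   finite values and non-empty spatial dimensions.
#' @return numeric vector z of length C with the spatial mean of each channel.
#' @export
#' @examples
#' x <- array(seq_len(2 * 2 * 3), c(2, 2, 3))
#' se_squeeze(x)  # 2.5 6.5 10.5
se_squeeze <- function(x) {
  d <- dim(x)
  if (length(d) != 3) stop_invalid("expected a 3-d feature map (H, W, C)")
  if (d[1] < 1 || d[2] < 1) stop_invalid("feature map has empty spatial dimensions")
  colMeans(matrix(x, d[1] * d[2], d[3]))
}

#' Excitation: bottleneck MLP with sigmoid gate
#'
#' Computes s = sigmoid(w2 relu(w1 z + b1) + b2). Every output lies strictly
#' inside (0, 1).
#'
#' @param z squeezed channel vector of length C.
#' @param w1 matrix (C/r) x C.
#' @param b1 bias vector of length C/r (default zeros).
#' @param w2 matrix C x (C/r).
#' @param b2 bias vector of length C (default zeros).
#' @return channel weight vector s of length C.
#' @export
#' @examples
#' se_excite(1, w1 = matrix(1), w2 = matrix(1))  # sigmoid(1) = 0.7311
se_excite <- function(z, w1, w2, b1 = numeric(nrow(w1)), b2 = numeric(nrow(w2))) {
  if (ncol(w1) != length(z))
    stop_invalid("w1 has %d columns but z has length %d", ncol(w1), length(z))
  if (ncol(w2) != nrow(w1) || nrow(w2) != length(z))
    stop_invalid("w2 must be %d x %d, got %d x %d",
                 length(z), nrow(w1), nrow(w2), ncol(w2))
  as.vector(sigmoid(w2 %*% relu(w1 %*% z + b1) + b2))
}

#' Apply a squeeze-and-excitation block to a feature map
#'
#' Gates each channel of `x` by its excitation weight: out(c, i, j) =
#' s_c x(c, i, j). Shape is preserved and, because 0 < s_c < 1, the output is
#' elementwise attenuated in absolute value.
#'
#' @param x numeric array of dim (H, W, C).
#' @param params an `se_params` object whose channel count matches `x`.
#' @return array of the same dim as `x`.
#' @export
se_apply <- function(x, params) {
  d <- dim(x)
  if (length(d) != 3) stop_invalid("expected a 3-d feature map (H, W, C)")
  if (d[3] != params$channels)
    stop_invalid("SE block has %d channels but feature map has %d",
                 params$channels, d[3])
  s <- se_excite(se_squeeze(x), params$w1, params$w2, params$b1, params$b2)
  x * rep(s, each = d[1] * d[2])
}

# ---- batched internals used by the network (layout (H, W, C, N)) ----

se_fw_batch <- function(x, params) {
  d <- dim(x)
  z <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  a <- params$w1 %*% z + params$b1
  h <- relu(a)
  s <- sigmoid(params$w2 %*% h + params$b2)
  out <- x * rep(as.vector(s), each = d[1] * d[2])
  list(out = out, z = z, h = h, s = s)
}

se_bw_batch <- function(x, cache, gout, params) {
  d <- dim(x)
  hw <- d[1] * d[2]
  sfull <- rep(as.vector(cache$s), each = hw)
  gx <- gout * sfull
  # ds_cn = sum_ij gout * x
  gs <- matrix(colSums(matrix(gout * x, hw, d[3] * d[4])), d[3], d[4])
  gpre2 <- gs * cache$s * (1 - cache$s)
  gw2 <- gpre2 %*% t(cache$h)
  gb2 <- rowSums(gpre2)
  gh <- t(params$w2) %*% gpre2
  gpre1 <- gh * (cache$h > 0)
  gw1 <- gpre1 %*% t(cache$z)
  gb1 <- rowSums(gpre1)
  gz <- t(params$w1) %*% gpre1
  gx <- gx + rep(as.vector(gz), each = hw) / hw
  list(gx = gx, gw1 = gw1, gb1 = gb1, gw2 = gw2, gb2 = gb2)
}
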