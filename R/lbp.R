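# Uniform Local Binary Pattern texture codes (P = 8, R = 1).
#
# A pixel's raw LBP code thresholds the 8 ring neighbours against the centre
# (ties count as 1) and packs the bits with weights 2^p. The "uniform"
# mapping keeps the 58 codes whose circular bit string has at most two 0/1
# transitions as distinct bins 0..57 and collapses everything else into a
# miscellaneous bin 58, for 59 bins in total. This is the
# non-rotation-invariant uniform ("u2") mapping: only it yields 59 patterns
# for P = 8.

# Ring order: the 8 integer-offset neighbours of the 3x3 square, clockwise
# from the top-left, bit p weighted 2^p. Offsets are (drow, dcol).
.lbp_ring <- matrix(c(-1, -1, -1,  0, -1,  1,  0,  1,
                       1,  1,  1,  0,  1, -1,  0, -1),
                    ncol = 2, byrow = TRUE)

#' Convert an RGB image to 8-bit grayscale
#'
#' Uses ITU-R BT.601 luma weights (0.299, 0.587, 0.114) and rounds half up to
#' integers, so an equal-channel pixel maps to its own value exactly.
#'
#' @param rgb numeric array of dim (H, W, 3) with intensities in \[0, 255\].
#' @return integer-valued matrix (H x W) of intensities in \[0, 255\].
#' @export
#' @examples
#' img <- array(128, c(4, 4, 3))
#' to_grayscale(img)[1, 1]  # 128
to_grayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3)
    stop_invalid("expected an image with exactly 3 colour planes, got %s",
                 if (length(d) == 3) d[3] else length(d))
  .gray601(rgb)
}

#' Raw 8-bit LBP code of a single pixel
#'
#' Computes sum_p s(g_p - g_c) 2^p over the 8 ring neighbours, with the sign
#' function s(x) = 1 for x >= 0 and 0 otherwise (ties count as "not darker").
#'
#' @param center centre intensity g_c.
#' @param neighbors ordered vector of the 8 neighbour intensities g_p
#'   (clockwise from the top-left of the 3x3 square).
#' @return integer in \[0, 255\].
#' @export
#' @examples
#' lbp_raw_code(5, rep(5, 8))               # 255
#' lbp_raw_code(5, c(9, 0, 9, 0, 9, 0, 9, 0)) # 85
lbp_raw_code <- function(center, neighbors) {
  if (length(neighbors) != 8)
    stop_invalid("expected exactly 8 neighbor intensities, got %d", length(neighbors))
  sum(as.integer(neighbors >= center) * 2L^(0:7))
}

#' Build the 59-bin uniform LBP mapping table
#'
#' Enumerates all 256 raw 8-bit codes, counts circular 0/1 transitions (bit 7
#' adjacent to bit 0), assigns the 58 codes with at most two transitions
#' distinct bins 0..57 in increasing raw-code order, and maps all remaining
#' codes to the miscellaneous bin 58.
#'
#' @return a list of class `uniform_mapping` with elements `table` (integer
#'   vector of length 256, entry `i` is the bin of raw code `i - 1`) and
#'   `n_uniform` (number of uniform codes, 58).
#' @export
#' @examples
#' m <- build_uniform_mapping()
#' m$n_uniform                    # 58
#' length(unique(m$table))        # 59
build_uniform_mapping <- function() {
  codes <- 0:255
  bits <- t(sapply(codes, function(cc) as.integer(intToBits(cc))[1:8]))
  trans <- rowSums(bits != bits[, c(2:8, 1)])
  uniform <- trans <= 2
  table <- integer(256)
  table[uniform] <- seq_len(sum(uniform)) - 1L   # bins 0..57, ascending raw code
  table[!uniform] <- 58L
  structure(list(table = table, n_uniform = sum(uniform)),
            class = "uniform_mapping")
}

# Mapping table is a pure function of P = 8; compute once per session.
.lbp_env <- new.env(parent = emptyenv())
.uniform_table <- function() {
  if (is.null(.lbp_env$table)) .lbp_env$table <- build_uniform_mapping()$table
  .lbp_env$table
}

#' Uniform LBP code image of a grayscale image
#'
#' Computes the raw P = 8, R = 1 code at every pixel over the replicate-padded
#' image (so output dimensions equal input dimensions) and maps raw codes
#' through the 59-bin uniform table. The ring is realised as the 8
#' integer-offset neighbours of the 3x3 square, without sub-pixel
#' interpolation. Only the (P = 8, R = 1) configuration is implemented.
#'
#' @param img numeric matrix (H x W), H, W >= 3, intensities in \[0, 255\].
#' @param P number of ring neighbours; only 8 is supported.
#' @param R ring radius; only 1 is supported.
#' @return integer matrix (H x W) of bin indices in \[0, 58\].
#' @export
#' @examples
#' codes <- lbp_transform(matrix(7, 5, 5))
#' unique(as.vector(codes))  # the all-ones pattern's bin
lbp_transform <- function(img, P = 8, R = 1) {
  if (P != 8 || R != 1)
    stop(structure(class = c("lbpfuse_not_implemented", "error", "condition"),
                   list(message = sprintf(
                     "only the (P = 8, R = 1) configuration is implemented, got (P = %s, R = %s)",
                     P, R), call = sys.call())))
  if (!is.matrix(img)) img <- as.matrix(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3)
    stop_invalid("image must be at least 3x3 for a full radius-1 ring, got %dx%d", h, w)
  .lbp_u2(img, .uniform_table())
}

#' Rescale LBP bin indices to 8-bit intensities
#'
#' Maps bin b to round_half_up(b * 255 / 58), an order-preserving, injective
#' stretch of the 59 bins onto \[0, 255\] for input into the texture branch.
#'
#' @param codes matrix (or vector) of bin indices in \[0, 58\].
#' @return numeric array of the same shape with values in \[0, 255\].
#' @export
#' @examples
#' rescale_codes(c(0, 29, 58))  # 0 128 255
rescale_codes <- function(codes) {
  if (any(codes < 0 | codes > 58))
    stop_invalid("bin indices must lie in [0, 58]")
  round_half_up(codes * 255 / 58)
}
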