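# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: the LBP oracle is a naive per-pixel double loop
# and the uniformity oracle counts transitions on explicit bit strings.

# naive double-loop uniform LBP (replicate padding, ring clockwise from the
# top-left 3x3 neighbour, bit weight 2^p, ties >= count as 1)
naive_lbp_oracle <- function(img, table = NULL) {
  if (is.null(table)) table <- oracle_uniform_table()
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(1, 1:h, h), c(1, 1:w, w)]
  ring <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                 ncol = 2, byrow = TRUE)
  out <- matrix(0L, h, w)
  for (y in 1:h) {
    for (x in 1:w) {
      code <- 0L
      for (p in 1:8) {
        ny <- y + 1 + ring[p, 1]
        nx <- x + 1 + ring[p, 2]
        if (pad[ny, nx] >= img[y, x]) code <- code + 2L^(p - 1)
      }
      out[y, x] <- table[code + 1L]
    }
  }
  out
}

# circular transition count from the explicit bit string of a code
oracle_transitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != c(bits[-1], bits[1]))
}

# mapping table built straight from the definition, independent of the
# package's vectorised construction
oracle_uniform_table <- function() {
  trans <- vapply(0:255, oracle_transitions, integer(1))
  tab <- integer(256)
  uni <- which(trans <= 2)          # already in increasing raw-code order
  tab[uni] <- seq_along(uni) - 1L
  tab[trans > 2] <- 58L
  tab
}

random_gray_image <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# a small random RGB array in [0, 255]
random_rgb_image <- function(h = 32, w = 32) {
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}
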