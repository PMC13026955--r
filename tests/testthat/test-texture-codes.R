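# Uniform LBP texture codes

test_that("grayscale conversion uses BT.601 luma with half-up rounding", {
  for (v in c(0, 1, 87, 128, 255))
    expect_equal(to_grayscale(array(v, c(2, 2, 3)))[1, 1], v)
  expect_equal(to_grayscale(array(c(255, 0, 0), c(1, 1, 3)))[1, 1], 76)
  expect_equal(to_grayscale(array(0, c(3, 3, 3))), matrix(0, 3, 3))
  err <- expect_error(to_grayscale(array(0, c(2, 2, 4))),
                      class = "lbpfuse_invalid_input")
  expect_match(conditionMessage(err), "4")
})

test_that("raw LBP codes implement the thresholded bit sum with ties as 1", {
  expect_equal(lbp_raw_code(5, rep(5, 8)), 255)      # s(0) = 1
  expect_equal(lbp_raw_code(9, c(8, 3, 0, 1, 2, 5, 7, 8)), 0)
  expect_equal(lbp_raw_code(5, c(9, 0, 9, 0, 9, 0, 9, 0)), 85)
  # independent bit-string oracle on random cases
  set.seed(71)
  for (i in 1:60) {
    ctr <- sample(0:255, 1)
    nb <- sample(0:255, 8, replace = TRUE)
    bits <- rev(as.integer(nb >= ctr))               # bit 7 ... bit 0
    expect_equal(lbp_raw_code(ctr, nb),
                 strtoi(paste(bits, collapse = ""), base = 2))
  }
  expect_error(lbp_raw_code(5, 1:7), class = "lbpfuse_invalid_input")
})

test_that("the uniform mapping has 58 uniform codes and 59 bins", {
  m <- build_uniform_mapping()
  expect_length(m$table, 256)
  expect_equal(m$n_uniform, 58)
  expect_equal(length(unique(m$table)), 59)
  # exhaustive check against the transition-count oracle
  trans <- vapply(0:255, oracle_transitions, integer(1))
  expect_equal(sum(trans <= 2), 58)
  expect_true(all(m$table[trans > 2] == 58))
  # uniform codes get bins 0..57 bijectively, ascending in raw-code order
  expect_equal(m$table[trans <= 2], 0:57)
  expect_identical(m$table, oracle_uniform_table())
})

test_that("lbp_transform matches a naive double-loop oracle bit-exactly", {
  set.seed(13)
  for (i in 1:120) {
    h <- sample(3:32, 1); w <- sample(3:32, 1)
    img <- random_gray_image(h, w)
    expect_identical(lbp_transform(img), naive_lbp_oracle(img))
  }
})

test_that("constant images map everywhere to the all-ones pattern's bin", {
  m <- build_uniform_mapping()
  codes <- lbp_transform(matrix(7, 6, 9))
  expect_true(all(codes == m$table[256]))            # raw code 255
})

test_that("an alternating ring around the centre lands in the miscellaneous bin", {
  img <- matrix(c(9, 0, 9, 0, 5, 0, 9, 0, 9), 3, 3)  # raw 85: 8 transitions
  expect_equal(lbp_transform(img)[2, 2], 58)
})

test_that("codes are invariant to intensity shifts and covariant to shifts", {
  set.seed(29)
  img <- random_gray_image(20, 17)
  expect_identical(lbp_transform(img), lbp_transform(img + 40))
  # translating the input translates interior codes identically
  full <- lbp_transform(img)
  crop <- lbp_transform(img[3:20, 4:17])
  expect_identical(crop[2:(nrow(crop) - 1), 2:(ncol(crop) - 1)],
                   full[4:19, 5:16])
})

test_that("only the (P = 8, R = 1) configuration is accepted", {
  img <- random_gray_image(5, 5)
  err <- expect_error(lbp_transform(img, P = 16, R = 2),
                      class = "lbpfuse_not_implemented")
  expect_match(conditionMessage(err), "P = 8, R = 1")
  expect_error(lbp_transform(matrix(1, 2, 5)), class = "lbpfuse_invalid_input")
})

test_that("code rescaling is the injective half-up stretch onto [0, 255]", {
  expect_equal(rescale_codes(0), 0)
  expect_equal(rescale_codes(58), 255)
  expect_equal(rescale_codes(29), 128)               # 127.5 rounds up
  v <- rescale_codes(0:58)
  expect_equal(length(unique(v)), 59)                # injective
  expect_true(all(diff(v) > 0))                      # order-preserving
  expect_error(rescale_codes(59), class = "lbpfuse_invalid_input")
})
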