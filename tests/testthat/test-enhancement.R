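test_that("dct2/idct2 match the direct double-sum definition and invert", {
  set.seed(42)
  # definition oracle on 4x4 blocks
  for (rep in 1:5) {
    b <- matrix(rnorm(16, sd = 50), 4, 4)
    expect_lt(max(abs(dct2(b) - dct2_direct(b))), 1e-10)
  }
  # constant block: DC = side * c, AC = 0
  D <- dct2(matrix(3, 8, 8))
  expect_equal(D[1, 1], 24)
  expect_lt(max(abs(D[-1])), 1e-12)
  expect_lt(max(abs(D[1, -1])), 1e-12)
  # identity on 1x1
  expect_equal(dct2(matrix(7, 1, 1)), matrix(7, 1, 1))
  # round trips up to 32x32
  for (n in c(2, 8, 17, 32)) {
    x <- matrix(rnorm(n * n, sd = 100), n, n)
    expect_lt(max(abs(idct2(dct2(x)) - x)), 1e-8)
  }
  # DC-only coefficients reconstruct a constant block
  co <- matrix(0, 8, 8); co[1, 1] <- 8 * 2.5
  expect_lt(max(abs(idct2(co) - 2.5)), 1e-12)
  expect_equal(idct2(matrix(0, 5, 5)), matrix(0, 5, 5))
  # invalid input
  expect_error(dct2(matrix(0, 2, 3)), "square")
  expect_error(dct2("x"), "numeric")
})

test_that("power spectrum satisfies Parseval's identity", {
  expect_equal(power_spectrum(matrix(0, 4, 4)), matrix(0, 4, 4))
  P <- power_spectrum(dct2(matrix(1, 8, 8)))
  expect_equal(P[1, 1], 64)
  expect_lt(sum(P) - P[1, 1], 1e-12)
  set.seed(7)
  for (n in c(4, 8, 16)) {
    x <- matrix(rnorm(n * n, sd = 30), n, n)
    P <- power_spectrum(dct2(x))
    expect_lt(abs(sum(P) - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("zigzag_order enumerates antidiagonals low to high frequency", {
  expect_equal(zigzag_order(1), matrix(c(0L, 0L), 1, 2,
                                       dimnames = list(NULL, c("u", "v"))))
  z2 <- zigzag_order(2)
  expect_equal(unname(z2), matrix(c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L), 4, 2))
  z8 <- zigzag_order(8)
  expect_equal(nrow(z8), 64)
  expect_equal(unname(z8[1:3, ]), matrix(c(0L, 0L, 1L, 0L, 1L, 0L), 3, 2))
  # every position appears exactly once, frequencies non-decreasing in sum
  expect_equal(sort(z8[, 1] * 8 + z8[, 2]), 0:63)
  expect_true(all(diff(rowSums(z8)) %in% c(-1L, 0L, 1L)))
  expect_error(zigzag_order(0), ">= 1")
})

test_that("split_frequency is additive and respects the cutoff", {
  set.seed(11)
  img <- gray_image(matrix(sample(0:255, 16 * 16, TRUE), 16, 16), "uint8")
  for (cutoff in c(1, 5, 16, 64)) {
    s <- split_frequency(img, block_size = 8, lf_cutoff = cutoff)
    expect_lt(max(abs(s$lf_image + s$hf_image - img)), 1e-8)
  }
  # full cutoff: everything is LF
  s <- split_frequency(img, lf_cutoff = 64)
  expect_lt(max(abs(s$lf_image - img)), 1e-8)
  expect_lt(max(abs(s$hf_image)), 1e-8)
  # DC-only cutoff on a constant image: LF = image, HF = 0
  cimg <- gray_image(matrix(100, 16, 16), "uint8")
  s <- split_frequency(cimg, lf_cutoff = 1)
  expect_lt(max(abs(s$lf_image - 100)), 1e-10)
  expect_lt(max(abs(s$hf_image)), 1e-10)
  # non-multiple sizes survive the padding policy
  odd <- gray_image(matrix(sample(0:255, 13 * 21, TRUE), 13, 21), "uint8")
  s <- split_frequency(odd, lf_cutoff = 10)
  expect_equal(dim(s$lf_image), c(13L, 21L))
  expect_lt(max(abs(s$lf_image + s$hf_image - odd)), 1e-8)
  expect_error(split_frequency(img, lf_cutoff = 65), "lf_cutoff")
  expect_error(split_frequency(img, lf_cutoff = 0), "lf_cutoff")
})

test_that("clahe respects range, identity and constant contracts", {
  # constant image maps to itself
  cimg <- gray_image(matrix(42, 32, 32), "uint8")
  expect_equal(as.vector(clahe(cimg)), rep(42, 32 * 32))
  # single tile, generous clip, uniform histogram: ~identity
  set.seed(3)
  u <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64), "uint8")
  out <- clahe(u, clip_limit = 1, tile_grid = c(1, 1))
  expect_lte(max(abs(as_mat(out) - as_mat(u))), 4)  # one-bin quantization slack
  # output bounded by the input's global display range
  set.seed(4)
  r <- gray_image(matrix(sample(40:200, 48 * 48, TRUE), 48, 48), "uint8")
  out <- clahe(r)
  expect_gte(min(out), 40)
  expect_lte(max(out), 200)
  expect_error(clahe(r, clip_limit = 0), "clip_limit")
  expect_error(clahe(gray_image(matrix(0, 4, 4), "HU")), "window")
})

test_that("enhance leaves the high-frequency residual untouched", {
  set.seed(5)
  px <- matrix(pmin(pmax(round(120 + 25 * matrix(rnorm(64 * 64), 64)), 0), 255),
               64, 64)
  img <- gray_image(px, "uint8")
  res <- enhance(img, details = TRUE)
  ref <- split_frequency(img)
  expect_equal(as_mat(res$hf_image), as_mat(ref$hf_image))
  expect_true(image_domain(res$enhanced) == "uint8")
  # constant image passes through
  cimg <- gray_image(matrix(77, 32, 32), "uint8")
  expect_equal(as.vector(enhance(cimg)), rep(77, 32 * 32))
  # low-contrast phantom slice gains contrast inside the anatomy (globally
  # the air background dominates the variance, so the lung interior is the
  # meaningful place to measure the enhancement)
  ph <- generate_slice(test_phantom_spec(seed = 21, contrast_degradation = 0.5))
  win <- window_to_uint8(ph$image)
  enh <- enhance(ph$image)
  lung <- ph$truth$lung_mask
  expect_gte(sd(enh[lung]), sd(win[lung]))
})
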