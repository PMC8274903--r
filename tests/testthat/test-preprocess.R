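test_that("split_channels returns the planes unchanged and validates shape", {
  rgb <- array(0, c(4, 5, 3))
  rgb[, , 1] <- 10; rgb[, , 2] <- 20; rgb[, , 3] <- 30
  ch <- split_channels(rgb)
  expect_equal(ch$red, matrix(10, 4, 5))
  expect_equal(ch$green, matrix(20, 4, 5))
  expect_equal(ch$blue, matrix(30, 4, 5))

  px <- array(c(255, 0, 0), c(1, 1, 3))
  ch <- split_channels(px)
  expect_equal(as.vector(ch$red), 255)
  expect_equal(as.vector(ch$green), 0)

  set.seed(1)
  r <- array(runif(6 * 7 * 3), c(6, 7, 3))
  expect_identical(dim(split_channels(r)$blue), c(6L, 7L))
  expect_error(split_channels(array(0, c(4, 4, 2))), "3")
})

test_that("fuse_grayscale computes the weighted rounded fusion", {
  w <- c(0.299, 0.587, 0.114)
  const <- array(100, c(3, 3, 3))
  expect_equal(fuse_grayscale(const, w), matrix(100, 3, 3))
  # red-only pixel: independent arithmetic oracle
  red <- array(c(255, 0, 0), c(1, 1, 3))
  expect_equal(as.vector(fuse_grayscale(red, w)),
               floor(0.299 * 255 + 0.5))
  # (1,0,0) weights reproduce the red plane exactly
  set.seed(42)
  rgb <- array(sample(0:255, 8 * 9 * 3, TRUE), c(8, 9, 3))
  expect_equal(fuse_grayscale(rgb, c(1, 0, 0)), split_channels(rgb)$red)
  expect_error(fuse_grayscale(rgb, c(-0.1, 0.6, 0.5)), "non-negative")
  # defaults are the published fusion ratio
  expect_equal(preprocess_config()$channel_weights, c(0.299, 0.587, 0.114))
})

test_that("normalization standardizes then rescales to [0, 255]", {
  expect_equal(normalize_image(matrix(7, 5, 5)), array(127.5, c(5, 5)))
  two <- matrix(c(0, 255), 4, 4)
  out <- normalize_image(two)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  set.seed(3)
  r <- matrix(rnorm(400, 50, 20), 20, 20)
  out <- normalize_image(r)
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  # affine rescale preserves the z-score ordering
  expect_equal(order(out), order(r))
})

test_that("CLAHE preserves constants, expands low contrast, keeps shape", {
  const <- matrix(90, 32, 32)
  out <- clahe(const)
  expect_equal(length(unique(as.vector(out))), 1L)
  # low-contrast gradient: dynamic range must not shrink
  grad <- matrix(rep(seq(100, 120, length.out = 64), each = 64), 64, 64)
  out <- clahe(grad, clip_limit = 2, tile_grid = c(4, 4))
  expect_gte(diff(range(out)), diff(range(grad)))
  expect_identical(dim(out), dim(grad))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  expect_error(clahe(grad, clip_limit = 0), "positive")
})

test_that("gamma correction matches the power law and is monotone", {
  v <- matrix(0:255, 16, 16)
  expect_equal(gamma_correct(v, 1), v)
  expect_equal(as.vector(gamma_correct(matrix(255), 1.2)), 255)
  # independent arithmetic oracle for the half-gray value
  expect_equal(as.vector(gamma_correct(matrix(128), 1.2)),
               floor(255 * (128 / 255)^1.2 + 0.5))
  # exhaustive monotonicity over all 256 inputs: strict before rounding,
  # non-decreasing after
  x <- 0:255
  cont <- 255 * (x / 255)^1.2
  expect_true(all(diff(cont) > 0))
  expect_true(all(diff(as.vector(gamma_correct(matrix(x, 1), 1.2))) >= 0))
  expect_error(gamma_correct(v, 0), "positive")
})

test_that("the pipeline applies fusion, normalization, CLAHE, gamma in order", {
  cfg <- preprocess_config()
  const <- array(77, c(16, 16, 3))
  out <- preprocess_image(const, cfg)
  expect_equal(length(unique(as.vector(out))), 1L)
  expect_identical(dim(out), c(16L, 16L))
  set.seed(9)
  rgb <- array(sample(0:255, 32 * 40 * 3, TRUE), c(32, 40, 3))
  out <- preprocess_image(rgb, cfg)
  expect_identical(dim(out), c(32L, 40L))
  expect_gte(min(out), 0)
  expect_lte(max(out), 255)
  # composition oracle: running the four stages by hand gives the same map
  byhand <- gamma_correct(
    clahe(normalize_image(fuse_grayscale(rgb, cfg$channel_weights)),
          cfg$clahe_clip_limit, cfg$clahe_tile_grid),
    cfg$gamma)
  expect_equal(out, byhand)
})
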