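test_that("pad_to_grid finds the smallest stride-aligned canvas", {
  p <- pad_to_grid(matrix(1, 565, 584), 48, 48)
  expect_equal(p$padded_shape, c(576L, 624L))
  expect_equal(pad_to_grid(matrix(1, 96, 96), 48, 48)$padded_shape, c(96L, 96L))
  expect_equal(pad_to_grid(matrix(1, 50, 50), 48, 5)$padded_shape, c(53L, 53L))
  # padding is black and the original content is preserved
  img <- matrix(7, 50, 50)
  p <- pad_to_grid(img, 48, 5)
  expect_equal(p$image[1:50, 1:50], img)
  expect_true(all(p$image[51:53, ] == 0))
  expect_error(pad_to_grid(img, 48, 49), "stride")
})

test_that("grid extraction enumerates the closed-form window count", {
  p <- pad_to_grid(matrix(rnorm(565 * 584), 565, 584), 48, 48)
  ps <- extract_grid_patches(p)
  expect_equal(dim(ps$patches)[3], 156L)
  # randomized property: count always matches the window formula
  set.seed(11)
  for (q in 1:20) {
    S <- sample(4:12, 1)
    st <- sample(seq_len(S), 1)
    H <- S + st * sample(0:5, 1)
    W <- S + st * sample(0:5, 1)
    ps <- extract_grid_patches(matrix(0, H, W), S, st)
    expect_equal(dim(ps$patches)[3],
                 ((H - S) / st + 1) * ((W - S) / st + 1))
  }
  # a 48x48 input is its own single patch
  img <- matrix(rnorm(48 * 48), 48, 48)
  ps <- extract_grid_patches(img, 48, 5)
  expect_equal(dim(ps$patches)[3], 1L)
  expect_equal(ps$patches[, , 1], img)
  expect_error(extract_grid_patches(matrix(0, 50, 50), 48, 48), "padded")
})

test_that("random patch sampling is seeded and keeps image/mask aligned", {
  img <- coded_image(80, 90)
  mask <- img %% 7
  fov <- matrix(1, 80, 90)
  a <- sample_random_patches(img, mask, fov, 25, 48, seed = 5)
  b <- sample_random_patches(img, mask, fov, 25, 48, seed = 5)
  expect_identical(a$coords, b$coords)
  expect_identical(a$patches, b$patches)
  # alignment: the coded values confirm identical cut coordinates
  for (q in seq_len(dim(a$patches)[3])) {
    expect_equal(a$mask_patches[, , q], a$patches[, , q] %% 7)
    expect_equal(a$patches[1, 1, q],
                 unname(img[a$coords[q, 1] + 1, a$coords[q, 2] + 1]))
  }
  # a 48x48 image with full FOV admits only position (0, 0)
  one <- sample_random_patches(matrix(1, 48, 48), matrix(0, 48, 48),
                               matrix(1, 48, 48), 3, 48)
  expect_true(all(one$coords == 0L))
  expect_error(
    sample_random_patches(img, mask, matrix(0, 80, 90), 5, 48),
    "FOV")
})

test_that("reconstruction averages overlaps and inverts disjoint tiling", {
  # stride = S: exact round trip
  img <- matrix(runif(96 * 144), 96, 144)
  ps <- extract_grid_patches(img, 48, 48)
  expect_equal(reconstruct_from_patches(ps), img)
  # two half-overlapping constant patches -> 0.5 in the overlap
  ps2 <- structure(list(
    patches = array(rep(c(0, 1), each = 48 * 48), c(48, 48, 2)),
    coords = cbind(row = c(0L, 0L), col = c(0L, 24L)),
    padded_shape = c(48L, 72L), original_shape = c(48L, 72L),
    patch_size = 48L, stride = 24L, source_id = ""), class = "patch_set")
  rec <- reconstruct_from_patches(ps2)
  expect_true(all(rec[, 1:24] == 0))
  expect_true(all(rec[, 25:48] == 0.5))
  expect_true(all(rec[, 49:72] == 1))
  # brute-force accumulate-and-divide oracle on a random overlapping grid
  img <- matrix(runif(58 * 63), 58, 63)
  p <- pad_to_grid(img, 16, 5)
  ps3 <- extract_grid_patches(p)
  ps3$patches <- array(runif(length(ps3$patches)), dim(ps3$patches))
  acc <- matrix(0, p$padded_shape[1], p$padded_shape[2])
  cnt <- matrix(0, p$padded_shape[1], p$padded_shape[2])
  for (q in seq_len(dim(ps3$patches)[3])) {
    rows <- ps3$coords[q, 1] + 1:16
    cols <- ps3$coords[q, 2] + 1:16
    acc[rows, cols] <- acc[rows, cols] + ps3$patches[, , q]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  oracle <- (acc / cnt)[1:58, 1:63]
  expect_equal(reconstruct_from_patches(ps3), oracle, tolerance = 1e-12)
})

test_that("binarization applies the threshold inside the FOV only", {
  prob <- matrix(0.5, 10, 10)
  fov <- matrix(0, 10, 10)
  fov[3:8, 3:8] <- 1
  expect_true(all(binarize_probmap(prob, 0.52, fov) == 0))
  b <- binarize_probmap(prob, 0, fov)
  expect_equal(b, fov)
  expect_equal(sum(binarize_probmap(prob, 0.5, fov)), 36)
  expect_error(binarize_probmap(prob, 1.2, fov), "threshold")
})
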