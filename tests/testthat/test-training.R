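test_that("the dihedral group generates 8 distinct variants of an asymmetric patch", {
  x <- coded_image(6, 6)
  orbit <- list()
  for (rot in 0:3) for (flip in c(FALSE, TRUE))
    orbit[[length(orbit) + 1L]] <- dihedral_transform(x, rot, flip)
  expect_length(unique(orbit), 8L)
  expect_identical(dihedral_transform(x, 0, FALSE), x)
  # four quarter turns return to the start
  expect_identical(dihedral_transform(x, 4, FALSE), x)
})

test_that("geometric augmentation keeps image and mask aligned", {
  img <- coded_image(12, 12)
  msk <- img %% 5
  set.seed(77)
  for (q in 1:10) {
    pr <- augment_pair(img, msk)
    expect_identical(pr$mask, pr$image %% 5)
  }
  off <- augment_pair(img, msk, geometric = FALSE)
  expect_identical(off$image, img)
  expect_identical(off$mask, msk)
})

test_that("local replacement swaps identical windows in images and masks", {
  a <- coded_image(48, 48); b <- -coded_image(48, 48)
  ma <- a %% 3; mb <- b %% 3
  set.seed(5)
  sw <- local_replacement(a, ma, b, mb)
  # values are conserved as a multiset
  expect_equal(sort(c(sw$img_a, sw$img_b)), sort(c(a, b)))
  # alignment: swapped masks still encode their images
  expect_identical(sw$msk_a, sw$img_a %% 3)
  expect_identical(sw$msk_b, sw$img_b %% 3)
  # something actually moved
  expect_false(identical(sw$img_a, a))
})

test_that("the learning-rate schedule starts at 1e-3 and decays by steps", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 1e-3)
  lrs <- lr_schedule(0:199, cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lr_schedule(99, cfg), 1e-3)
  expect_equal(lr_schedule(100, cfg), 1e-4)
  expect_equal(lr_schedule(150, cfg), 1e-5)
  expect_equal(lr_schedule(199, cfg), 1e-5)
})

test_that("leave-one-out folds cover every sample exactly once", {
  folds <- leave_one_out_split(20)
  expect_length(folds, 20L)
  expect_true(all(vapply(folds, function(f) length(f$train), 0L) == 19L))
  tests <- vapply(folds, function(f) f$test, 0L)
  expect_identical(sort(tests), 1:20)
  for (f in folds) expect_false(f$test %in% f$train)
  two <- leave_one_out_split(2)
  expect_identical(two[[1]]$train, 2L)
  expect_identical(two[[2]]$train, 1L)
  expect_error(leave_one_out_split(1), "at least 2")
})

test_that("training is bit-reproducible from the seed", {
  set.seed(99)
  S <- 48L
  patches <- array(runif(S * S * 20), c(S, S, 20))
  masks <- array(rbinom(S * S * 20, 1, 0.1), c(S, S, 20))
  cfg <- train_config(batch_size = 4L, max_steps = 3L, seed = 1234L,
                      n_patches = 20L)
  run_once <- function() {
    m <- build_mfinet(unet_config(base_width = 4L), seed = 1234L)
    train_mfinet(m, patches, masks, cfg)
  }
  m1 <- run_once()
  m2 <- run_once()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history$loss, m2$history$loss)
})

test_that("a width-reduced model overfits ten patches to near-zero loss", {
  set.seed(4)
  sm <- generate_sample(synth_config(seed = 500))
  g <- preprocess_image(sm$image)
  ps <- sample_random_patches(g, sm$vessel, sm$fov, 10, 48, seed = 7)
  cfg <- train_config(batch_size = 10L, max_steps = 150L, seed = 1234L,
                      n_patches = 10L, augment_geometric = FALSE,
                      augment_local_replacement = FALSE)
  # residual encoder-decoder: the identity shortcut is what lets a deep
  # stack overfit quickly (the plain double-conv baseline trains far slower)
  model <- build_mfinet(model_config(base_width = 8L, use_mr = FALSE,
                                     use_fas = FALSE), seed = 1234L)
  fit <- train_mfinet(model, ps$patches, ps$mask_patches, cfg)
  expect_lt(min(fit$history$loss), 0.05)
  expect_lt(mean(utils::tail(fit$history$loss, 10)), 0.05)
})
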