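test_that("indicator gates absent terms", {
  expect_identical(indicator(0), 0L)
  expect_identical(indicator(1), 1L)
  expect_identical(indicator(-2), 1L)
  expect_identical(indicator(c(0, 3, 0, -1)), c(0L, 1L, 1L)[c(1, 2, 1, 3)])
})

test_that("a residual unit with a zero branch is plain ReLU", {
  set.seed(2)
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4, 2))
  unit <- zero_params(init_residual_unit(4, 4))
  for (train in c(TRUE, FALSE)) {
    out <- residual_unit(x, unit, train = train)
    expect_equal(out, pmax(x, 0), tolerance = 1e-12)
  }
  # telescoping: a chain of zero-branch units leaves non-negative input alone
  xp <- pmax(x, 0)
  cur <- xp
  for (k in 1:3) cur <- residual_unit(cur, unit)
  expect_equal(cur, xp, tolerance = 1e-12)
})

test_that("residual units preserve spatial shape for any width pair", {
  x <- random_feature(10, 14, 3, 2)
  unit <- init_residual_unit(3, 7)
  out <- residual_unit(x, unit)
  expect_identical(dim(out), c(10L, 14L, 7L, 2L))
  expect_error(residual_unit(random_feature(4, 4, 5), unit), "channel")
})

test_that("spatial attention gives constant gates on constant inputs", {
  att <- init_spatial_attention(7)
  g <- spatial_attention(array(3.7, c(9, 9, 5)), att)
  # reflective padding makes the gate constant; single-precision gemm
  # blocking leaves sub-1e-6 rounding scatter
  expect_lt(diff(range(g)), 1e-6)
  x <- random_feature(12, 12, 6)
  g <- spatial_attention(x, att)
  expect_true(all(g > 0 & g < 1))
  expect_identical(dim(g), c(12L, 12L))
  # zero weights: sigma(0) = 0.5 everywhere
  g0 <- spatial_attention(x, zero_params(att))
  expect_equal(g0, matrix(0.5, 12, 12))
})

test_that("channel attention is spatially permutation invariant", {
  att <- init_channel_attention(8, reduction = 4)
  x <- random_feature(6, 6, 8)
  g <- channel_attention(x, att)
  expect_length(g, 8L)
  expect_true(all(g > 0 & g < 1))
  # permute pixels identically in every channel
  set.seed(5)
  perm <- sample(36)
  xp <- x
  for (c_ in 1:8) {
    m <- matrix(x[, , c_, 1][perm], 6, 6)
    xp[, , c_, 1] <- m
  }
  expect_equal(channel_attention(xp, att), g, tolerance = 1e-12)
  expect_equal(channel_attention(x, zero_params(att)), rep(0.5, 8))
  expect_error(init_channel_attention(4, reduction = 16), "reduction")
})

test_that("downsampling resample equals composed 2x poolings exactly", {
  set.seed(8)
  rs13 <- init_resample(1, 3, 3, 5)
  x <- random_feature(48, 48, 3, 2)
  out <- resample_to_level(x, rs13)
  expect_identical(dim(out), c(12L, 12L, 5L, 2L))
  # oracle: same conv, then two successive 2x poolings instead of one 4x
  conv <- mfinet:::.cpp_conv2d_fwd(x, rs13$params$rs.w, rs13$params$rs.b,
                                   1L, FALSE)
  once <- mfinet:::.cpp_maxpool_fwd(conv, 4L)$y
  twice <- mfinet:::.cpp_maxpool_fwd(mfinet:::.cpp_maxpool_fwd(conv, 2L)$y, 2L)$y
  expect_equal(once, twice, tolerance = 1e-12)
  expect_equal(out, once, tolerance = 1e-12)
})

test_that("upsampling resample matches a naive transposed-convolution oracle", {
  rs31 <- init_resample(3, 1, 4, 2)
  x <- random_feature(12, 12, 4, 1, seed = 3)
  out <- resample_to_level(x, rs31)
  expect_identical(dim(out), c(48L, 48L, 2L, 1L))
  # brute-force scatter in R
  w <- rs31$params$rs.w  # [4,4,cin,cout]
  b <- rs31$params$rs.b
  oracle <- array(0, c(48, 48, 2, 1))
  for (co in 1:2) {
    for (i in 1:12) for (j in 1:12) for (a in 1:4) for (bb in 1:4) {
      oracle[(i - 1) * 4 + a, (j - 1) * 4 + bb, co, 1] <-
        sum(x[i, j, , 1] * w[a, bb, , co])
    }
    oracle[, , co, 1] <- oracle[, , co, 1] + b[co]
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # same-level resample is the identity copy
  rs22 <- init_resample(2, 2, 4, 4)
  expect_identical(resample_to_level(x, rs22), x)
  expect_error(init_resample(2, 2, 4, 6), "channels")
  expect_error(resample_to_level(random_feature(10, 10, 3), init_resample(1, 3, 3, 4)),
               "divisible")
})

test_that("MR fusion drops absent levels via the indicator", {
  model <- build_mfinet(tiny_config(), seed = 21)
  r1 <- random_feature(16, 16, 2)
  r2 <- random_feature(8, 8, 3, seed = 2)
  # one-term fusion preserves the target's spatial shape
  f11 <- mr_fuse(model, list(r1), m = 1, stage = 1)
  expect_identical(dim(f11)[1:2], c(16L, 16L))
  # an explicit NULL level equals simply omitting it (A(.) = 0)
  f_null <- mr_fuse(model, list(r1, NULL), m = 1, stage = 2)
  f_short <- mr_fuse(model, list(r1), m = 1, stage = 2)
  expect_equal(f_null, f_short, tolerance = 1e-12)
  # two active levels: both are resampled to the target size before the sum
  f2 <- mr_fuse(model, list(r1, r2), m = 1, stage = 2)
  expect_identical(dim(f2)[1:2], c(16L, 16L))
  expect_false(isTRUE(all.equal(f2, f_short)))
  expect_error(mr_fuse(model, list(NULL, NULL), m = 1, stage = 2), "active")
})

test_that("MR generation halves resolution with one term per level", {
  model <- build_mfinet(tiny_config(), seed = 22)
  r1 <- random_feature(16, 16, 2)
  g <- mr_generate(model, list(r1), stage = 1)
  expect_identical(dim(g)[1:2], c(8L, 8L))
  r2 <- random_feature(8, 8, 3, seed = 4)
  g2 <- mr_generate(model, list(r1, r2), stage = 2)
  expect_identical(dim(g2)[1:2], c(4L, 4L))
  expect_identical(dim(g2)[3], 4L)
  expect_true(all(is.finite(g2)))
})

test_that("the MR module emits the full resolution pyramid", {
  model <- build_mfinet(model_config(base_width = 8L), seed = 23)
  x <- matrix(runif(48 * 48), 48, 48)
  pyr <- mr_module(model, x)
  expect_length(pyr, 5L)
  sizes <- vapply(pyr, function(p) dim(p)[1], 0L)
  expect_equal(sizes, c(48L, 24L, 12L, 6L, 3L))
  expect_equal(vapply(pyr, function(p) dim(p)[3], 0L),
               model$config$mr_widths)
  expect_true(all(vapply(pyr, function(p) all(is.finite(p)), NA)))
})

test_that("FAS differs from MR fusion only by the missing spatial gate", {
  cfg <- tiny_config()
  model <- build_mfinet(cfg, seed = 24)
  enc <- list(random_feature(16, 16, 2, seed = 1),
              random_feature(8, 8, 4, seed = 2),
              random_feature(4, 4, 8, seed = 3))
  s1 <- fas_aggregate(model, enc, m = 1)
  expect_identical(dim(s1), dim(enc[[1]]))
  # structural oracle: resample with the same weights, sum, channel-gate
  sum_terms <- enc[[1]]
  for (i in 2:3) {
    rs <- init_resample(i, 1, cfg$widths[i], cfg$widths[1])
    rs$params$rs.w <- model$params[[paste0("fas.m1.r", i, ".w")]]
    rs$params$rs.b <- model$params[[paste0("fas.m1.r", i, ".b")]]
    sum_terms <- sum_terms + resample_to_level(enc[[i]], rs)
  }
  ca <- init_channel_attention(cfg$widths[1], cfg$attn_reduction)
  for (nm in names(ca$params))
    ca$params[[nm]] <- model$params[[paste0("fas.m1.ca.", sub("^ca\\.", "", nm))]]
  gate <- channel_attention(sum_terms, ca)
  oracle <- sum_terms * array(rep(gate, each = 16 * 16), dim(sum_terms))
  expect_equal(s1, oracle, tolerance = 1e-10)
})

test_that("the forward pass yields per-pixel probability simplices", {
  for (variant in c("unet", "mi", "fas", "mr", "mrfas")) {
    model <- build_mfinet(ablation_config(variant, base_width = 4L), seed = 30)
    x <- array(runif(48 * 48), c(48, 48, 1, 1))
    p <- mfinet_forward(model, x)
    expect_identical(dim(p), c(48L, 48L, 2L, 1L))
    expect_equal(p[, , 1, ] + p[, , 2, ], matrix(1, 48, 48), tolerance = 1e-6)
    expect_identical(p, mfinet_forward(model, x))  # deterministic
  }
  expect_error(model_config(use_mr = TRUE, use_mi = TRUE), "exclusive")
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- tiny_config()
  n1 <- count_parameters(build_mfinet(cfg, seed = 1))
  n2 <- count_parameters(build_mfinet(cfg, seed = 999))
  expect_identical(n1, n2)
  # hand-counted single conv: 3x3, 1 -> 8 channels with bias
  B <- new.env(); B$p <- list()
  mfinet:::.mk_conv(B, "c", 3L, 3L, 1L, 8L)
  expect_identical(sum(lengths(B$p)), 1L * 8L * 9L + 8L)
})

test_that("network gradients agree with finite differences", {
  cfg <- tiny_config()
  model <- build_mfinet(cfg, seed = 11)
  set.seed(7)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  tgt <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  lossfn <- function(params) {
    m2 <- model
    m2$params <- params
    m2 <- mfinet:::.clone_model(m2)
    tp <- mfinet:::tg_tape(grad = FALSE)
    pn <- mfinet:::.param_nodes(m2$params)
    out <- mfinet:::.forward_net(tp, m2, pn, mfinet:::tg_leaf(x), TRUE)
    mfinet:::op_softmax_ce(tp, out$logits, tgt)$v
  }
  m2 <- mfinet:::.clone_model(model)
  tp <- mfinet:::tg_tape(grad = TRUE)
  pn <- mfinet:::.param_nodes(m2$params)
  out <- mfinet:::.forward_net(tp, m2, pn, mfinet:::tg_leaf(x), TRUE)
  loss <- mfinet:::op_softmax_ce(tp, out$logits, tgt)
  mfinet:::tg_backward(tp, loss)
  set.seed(13)
  for (nm in sample(names(model$params), 8)) {
    a <- model$params[[nm]]
    q <- sample(length(a), 1)
    eps <- 1e-3
    pp <- model$params; pp[[nm]][q] <- a[q] + eps
    pm <- model$params; pm[[nm]][q] <- a[q] - eps
    num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
    ana <- if (is.null(pn[[nm]]$g)) 0 else pn[[nm]]$g[q]
    # convolutions accumulate in single precision; tolerance reflects that
    expect_equal(ana, num, tolerance = 5e-3,
                 label = paste("grad", nm, "idx", q))
  }
})
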