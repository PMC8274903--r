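# Forward graph construction. Internal .xxx_nodes functions operate on tape
# nodes; the exported functions wrap plain arrays for standalone use.

.param_nodes <- function(params) lapply(params, tg_leaf)

# conv-bn-relu-conv-bn block; residual adds the (possibly projected)
# identity before the final ReLU, the plain variant just applies ReLU.
.block_forward <- function(tp, x, pn, S, name, residual, train) {
  h <- op_conv(tp, x, pn[[paste0(name, ".c1.w")]], pn[[paste0(name, ".c1.b")]], 1L)
  h <- op_bn(tp, h, pn[[paste0(name, ".bn1.g")]], pn[[paste0(name, ".bn1.be")]],
             S[[paste0(name, ".bn1")]], train)
  h <- op_relu(tp, h)
  f <- op_conv(tp, h, pn[[paste0(name, ".c2.w")]], pn[[paste0(name, ".c2.b")]], 1L)
  f <- op_bn(tp, f, pn[[paste0(name, ".bn2.g")]], pn[[paste0(name, ".bn2.be")]],
             S[[paste0(name, ".bn2")]], train)
  if (residual) {
    idn <- if (!is.null(pn[[paste0(name, ".proj.w")]])) {
      op_conv(tp, x, pn[[paste0(name, ".proj.w")]], pn[[paste0(name, ".proj.b")]], 0L)
    } else {
      x
    }
    f <- op_add(tp, f, idn)
  }
  op_relu(tp, f)
}

.sa_gate_nodes <- function(tp, x, pn, name, k) {
  mm <- op_chan_mean_max(tp, x)
  a <- op_conv(tp, mm, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
               (k - 1L) %/% 2L, reflect = TRUE)
  op_sigmoid(tp, a)
}

.ca_gate_nodes <- function(tp, x, pn, name) {
  mlp <- function(v) {
    h <- op_relu(tp, op_dense(tp, v, pn[[paste0(name, ".fc1.w")]],
                              pn[[paste0(name, ".fc1.b")]]))
    op_dense(tp, h, pn[[paste0(name, ".fc2.w")]], pn[[paste0(name, ".fc2.b")]])
  }
  g <- op_add(tp, mlp(op_gap(tp, x)), mlp(op_gmp(tp, x)))
  op_sigmoid(tp, g)  # [C, N]
}

.ca_apply_nodes <- function(tp, x, pn, name) {
  op_mul_gate(tp, x, op_as_cgate(tp, .ca_gate_nodes(tp, x, pn, name)))
}

.resample_nodes <- function(tp, x, i, m, pn, name) {
  if (i == m) return(x)
  if (i < m) {
    z <- op_conv(tp, x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]], 1L)
    op_maxpool(tp, z, 2L^(m - i))
  } else {
    op_convT(tp, x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]], 2L^(i - m))
  }
}

# act: list of per-level nodes (NULL = absent level, dropped by the
# indicator); target level m; parameters of fusion stage `stage`.
.mr_fuse_nodes <- function(tp, act, m, stage, pn, cfg) {
  base <- paste0("mr.s", stage, ".f", m)
  terms <- list()
  for (i in seq_along(act)) {
    if (is.null(act[[i]])) next
    z <- .resample_nodes(tp, act[[i]], i, m, pn, paste0(base, ".r", i))
    g <- .sa_gate_nodes(tp, z, pn, paste0(base, ".sa", i), cfg$spatial_kernel)
    terms[[length(terms) + 1L]] <- op_mul_gate(tp, z, g)
  }
  if (!length(terms)) stop("mr_fuse: no active levels")
  s <- if (length(terms) == 1L) terms[[1L]] else do.call(op_add, c(list(tp), terms))
  .ca_apply_nodes(tp, s, pn, paste0(base, ".ca"))
}

.mr_gen_nodes <- function(tp, act, stage, pn, cfg) {
  base <- paste0("mr.s", stage, ".gen")
  d <- tg_dims(act[[1L]]$v)
  if (d[1L] %/% 2L^stage < 1L) stop("mr_generate: target resolution below 1 pixel")
  terms <- list()
  for (i in seq_along(act)) {
    if (is.null(act[[i]])) next
    z <- op_conv(tp, act[[i]], pn[[paste0(base, ".r", i, ".w")]],
                 pn[[paste0(base, ".r", i, ".b")]], 1L)
    z <- op_maxpool(tp, z, 2L^(stage + 1L - i))
    g <- .sa_gate_nodes(tp, z, pn, paste0(base, ".sa", i), cfg$spatial_kernel)
    terms[[length(terms) + 1L]] <- op_mul_gate(tp, z, g)
  }
  if (!length(terms)) stop("mr_generate: no active levels")
  s <- if (length(terms) == 1L) terms[[1L]] else do.call(op_add, c(list(tp), terms))
  .ca_apply_nodes(tp, s, pn, paste0(base, ".ca"))
}

.mr_forward <- function(tp, x, pn, S, cfg, train) {
  r1 <- op_conv(tp, x, pn[["stem.w"]], pn[["stem.b"]], 1L)
  r1 <- op_bn(tp, r1, pn[["stem.bn.g"]], pn[["stem.bn.be"]], S[["stem.bn"]], train)
  r <- list(op_relu(tp, r1))
  for (s in seq_len(cfg$mr_stages)) {
    nxt <- vector("list", s + 1L)
    for (m in seq_len(s)) nxt[[m]] <- .mr_fuse_nodes(tp, r, m, s, pn, cfg)
    nxt[[s + 1L]] <- .mr_gen_nodes(tp, r, s, pn, cfg)
    r <- nxt
  }
  r
}

.fas_nodes <- function(tp, enc, m, pn, cfg) {
  base <- paste0("fas.m", m)
  terms <- lapply(seq_along(enc), function(i)
    .resample_nodes(tp, enc[[i]], i, m, pn, paste0(base, ".r", i)))
  s <- do.call(op_add, c(list(tp), terms))
  .ca_apply_nodes(tp, s, pn, paste0(base, ".ca"))
}

# mean 2^k-downscale of a [H,W,C,N] array (multi-scale input injection)
.avg_down <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  H <- d[1]; W <- d[2]
  m <- x
  dim(m) <- c(f, (H %/% f) * W * d[3] * d[4])
  m <- colMeans(m)
  dim(m) <- c(H %/% f, W, d[3], d[4])
  m <- aperm(m, c(2L, 1L, 3L, 4L))
  dim(m) <- c(f, (W %/% f) * (H %/% f) * d[3] * d[4])
  m <- colMeans(m)
  dim(m) <- c(W %/% f, H %/% f, d[3], d[4])
  aperm(m, c(2L, 1L, 3L, 4L))
}

# full graph; returns logits node plus intermediate features
.forward_net <- function(tp, model, pn, x, train) {
  cfg <- model$config
  S <- model$bn
  pyramid <- if (cfg$use_mr) .mr_forward(tp, x, pn, S, cfg, train) else NULL
  enc <- vector("list", cfg$n_levels)
  for (m in seq_len(cfg$n_levels)) {
    if (m == 1L) {
      xin <- if (cfg$use_mr) pyramid[[1L]] else x
    } else {
      inputs <- list(op_maxpool(tp, enc[[m - 1L]], 2L))
      if (cfg$use_mr) inputs <- c(inputs, list(pyramid[[m]]))
      if (cfg$use_mi) inputs <- c(inputs, list(tg_leaf(.avg_down(x$v, 2L^(m - 1L)))))
      xin <- op_concat_c(tp, inputs)
    }
    enc[[m]] <- .block_forward(tp, xin, pn, S, paste0("enc", m), cfg$use_residual, train)
  }
  d <- enc[[cfg$n_levels]]
  for (m in seq.int(cfg$n_levels - 1L, 1L)) {
    up <- op_convT(tp, d, pn[[paste0("up", m, ".w")]], pn[[paste0("up", m, ".b")]], 2L)
    skip <- if (cfg$use_fas) .fas_nodes(tp, enc, m, pn, cfg) else enc[[m]]
    xin <- op_concat_c(tp, list(up, skip))
    d <- .block_forward(tp, xin, pn, S, paste0("dec", m), cfg$use_residual, train)
  }
  logits <- op_conv(tp, d, pn[["head.w"]], pn[["head.b"]], 0L)
  list(logits = logits, enc = enc, pyramid = pyramid)
}

## ------- exported operations -------

#' Network forward pass
#'
#' Runs the configured network on one or more patches and returns per-pixel
#' class probabilities (softmax over the two output channels; channel 2 is
#' the vessel class).
#'
#' @param model a built `mfinet_model`.
#' @param x input patch: `[H,W]` matrix, `[H,W,1,N]` array, intensities in
#'   `[0,1]`.
#' @param train use batch statistics in batch norm (training mode) instead
#'   of running statistics.
#' @return probability array `[H,W,2,N]`; each pixel's channels sum to 1.
#' @export
mfinet_forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "mfinet_model"))
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(model$params)
  out <- .forward_net(tp, model, pn, tg_leaf(as_nhwc(x)), train)
  op_softmax_c(tp, out$logits)$v
}

#' Multi-resolution fusion input pyramid
#'
#' Runs the MR module alone: a stem convolution lifts the input image to the
#' first-level width, then each fusion stage updates all existing levels and
#' generates one new level at half resolution, producing `n_levels` feature
#' maps at sizes `S, S/2, ..., S/2^(n-1)`.
#'
#' @inheritParams mfinet_forward
#' @return list of `n_levels` feature arrays `[H_m, W_m, C_m, N]`.
#' @export
mr_module <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "mfinet_model"), model$config$use_mr)
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(model$params)
  r <- .mr_forward(tp, tg_leaf(as_nhwc(x)), pn, model$bn, model$config, train)
  lapply(r, function(nd) nd$v)
}

#' Single fusion update of one resolution level
#'
#' Resamples every active level to target level `m`, gates each with its
#' spatial attention, sums (absent levels, given as `NULL`, are dropped by
#' the indicator), and applies channel attention to the sum.
#'
#' @param model a built model with `use_mr = TRUE`.
#' @param features list of per-level feature arrays (or `NULL` for absent
#'   levels), levels `1..s` of fusion stage `stage`.
#' @param m target level.
#' @param stage fusion stage whose parameters to use (defaults to
#'   `length(features)`).
#' @return updated level-`m` feature array.
#' @export
mr_fuse <- function(model, features, m, stage = length(features)) {
  stopifnot(inherits(model, "mfinet_model"), model$config$use_mr)
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(model$params)
  act <- lapply(features, function(f) if (is.null(f)) NULL else tg_leaf(as_nhwc(f)))
  .mr_fuse_nodes(tp, act, m, stage, pn, model$config)$v
}

#' Generate the next (lower-resolution) level
#'
#' Every existing level is passed through a 3x3 convolution and max-pooled
#' down to the new level's resolution, spatially gated, summed, and channel
#' attention applied.
#'
#' @inheritParams mr_fuse
#' @param features list of feature arrays for levels `1..stage`.
#' @return the new level-`stage + 1` feature array.
#' @export
mr_generate <- function(model, features, stage = length(features)) {
  stopifnot(inherits(model, "mfinet_model"), model$config$use_mr)
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(model$params)
  act <- lapply(features, function(f) if (is.null(f)) NULL else tg_leaf(as_nhwc(f)))
  .mr_gen_nodes(tp, act, stage, pn, model$config)$v
}

#' Fully aggregated skip connection output
#'
#' Resamples every encoder level to decoder level `m`, sums them (no spatial
#' gating), and applies channel attention; the result is what the decoder
#' concatenates with its upsampled stream.
#'
#' @param model a built model with `use_fas = TRUE`.
#' @param encoder_features list of `n_levels` encoder feature arrays.
#' @param m target decoder level.
#' @return aggregated feature array at level-`m` resolution.
#' @export
fas_aggregate <- function(model, encoder_features, m) {
  stopifnot(inherits(model, "mfinet_model"), model$config$use_fas)
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(model$params)
  enc <- lapply(encoder_features, function(f) tg_leaf(as_nhwc(f)))
  .fas_nodes(tp, enc, m, pn, model$config)$v
}

## ---- standalone layer primitives ----

#' Standalone residual unit
#'
#' `init_residual_unit()` creates the parameters of one unit (two 3x3
#' convolutions with batch norm; a 1x1 projection when widths differ);
#' `residual_unit()` computes `ReLU(h(x) + F(x))` where `h` is the identity
#' (or the projection) and `F` the conv-norm-relu-conv-norm branch.
#'
#' @param in_ch,out_ch channel widths.
#' @param residual include the identity/shortcut branch (`FALSE` gives the
#'   plain double-convolution block used by the U-Net baseline).
#' @return `init_residual_unit`: a parameter bundle; `residual_unit`: the
#'   output feature array, same spatial shape as the input.
#' @export
init_residual_unit <- function(in_ch, out_ch, residual = TRUE) {
  B <- new.env(parent = emptyenv()); B$p <- list(); B$s <- list()
  .mk_block(B, "u", as.integer(in_ch), as.integer(out_ch), residual)
  structure(list(params = B$p, bn = B$s, residual = residual,
                 in_ch = in_ch, out_ch = out_ch),
            class = "mfinet_unit")
}

#' @rdname init_residual_unit
#' @param x input feature array (`[H,W]`, `[H,W,C]` or `[H,W,C,N]`).
#' @param unit parameters from `init_residual_unit()`.
#' @param train batch-norm mode.
#' @export
residual_unit <- function(x, unit, train = FALSE) {
  stopifnot(inherits(unit, "mfinet_unit"))
  x <- as_nhwc(x)
  if (dim(x)[3L] != unit$in_ch) stop("residual_unit: channel mismatch")
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(unit$params)
  .block_forward(tp, tg_leaf(x), pn, unit$bn, "u", unit$residual, train)$v
}

#' Standalone spatial attention gate
#'
#' Channel-wise average and max maps are stacked (2 channels), convolved
#' with a `kernel x kernel` filter (reflective padding, so a spatially
#' constant input yields an exactly constant gate) and passed through a
#' sigmoid. The caller multiplies the gate into the features.
#'
#' @param kernel odd kernel size.
#' @return `init_spatial_attention`: a parameter bundle; `spatial_attention`:
#'   the gate, `[H,W]` for a single feature map, `[H,W,1,N]` for a batch.
#' @export
init_spatial_attention <- function(kernel = 7L) {
  B <- new.env(parent = emptyenv()); B$p <- list()
  .mk_sa(B, "sa", as.integer(kernel))
  structure(list(params = B$p, kernel = as.integer(kernel)),
            class = "mfinet_sa")
}

#' @rdname init_spatial_attention
#' @param x feature array.
#' @param att parameters from `init_spatial_attention()`.
#' @export
spatial_attention <- function(x, att) {
  stopifnot(inherits(att, "mfinet_sa"))
  x <- as_nhwc(x)
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(att$params)
  g <- .sa_gate_nodes(tp, tg_leaf(x), pn, "sa", att$kernel)$v
  if (dim(x)[4L] == 1L) g <- matrix(g, dim(x)[1L], dim(x)[2L])
  g
}

#' Standalone channel attention gate
#'
#' Global average- and max-pooled channel vectors pass through a shared
#' two-layer MLP (hidden width `C / reduction`), are summed, and squashed by
#' a sigmoid. Invariant to any spatial permutation of the input.
#'
#' @param channels feature channel count.
#' @param reduction MLP reduction ratio; hidden width is
#'   `max(1, channels %/% reduction)`.
#' @return `init_channel_attention`: a parameter bundle; `channel_attention`:
#'   the per-channel gate (vector of length `C`, or `[C,N]` for a batch).
#' @export
init_channel_attention <- function(channels, reduction = 16L) {
  if (reduction > channels && channels > 1L)
    stop("channel attention: reduction larger than channel count")
  B <- new.env(parent = emptyenv()); B$p <- list()
  .mk_ca(B, "ca", as.integer(channels), as.integer(reduction))
  structure(list(params = B$p, channels = as.integer(channels)),
            class = "mfinet_ca")
}

#' @rdname init_channel_attention
#' @param x feature array.
#' @param att parameters from `init_channel_attention()`.
#' @export
channel_attention <- function(x, att) {
  stopifnot(inherits(att, "mfinet_ca"))
  x <- as_nhwc(x)
  if (dim(x)[3L] != att$channels) stop("channel_attention: channel mismatch")
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(att$params)
  g <- .ca_gate_nodes(tp, tg_leaf(x), pn, "ca")$v
  if (dim(x)[4L] == 1L) g <- as.vector(g)
  g
}

#' Standalone level resampling
#'
#' Moves a feature map from level `i` to level `m`: 3x3 convolution followed
#' by a `2^(m-i)` max pool when going down, a transposed convolution with
#' kernel and stride `2^(i-m)` when going up, and an identity copy at the
#' same level.
#'
#' @param i,m source and target levels.
#' @param in_ch,out_ch source and target channel widths (must be equal when
#'   `i == m`).
#' @return `init_resample`: a parameter bundle; `resample_to_level`: the
#'   resampled feature array at level-`m` spatial size.
#' @export
init_resample <- function(i, m, in_ch, out_ch) {
  if (i == m && in_ch != out_ch)
    stop("resample: the same-level copy preserves channels")
  B <- new.env(parent = emptyenv()); B$p <- list()
  .mk_resample(B, "rs", as.integer(i), as.integer(m),
               as.integer(in_ch), as.integer(out_ch))
  structure(list(params = B$p, i = as.integer(i), m = as.integer(m)),
            class = "mfinet_resample")
}

#' @rdname init_resample
#' @param x feature array at level `i`.
#' @param rs parameters from `init_resample()`.
#' @export
resample_to_level <- function(x, rs) {
  stopifnot(inherits(rs, "mfinet_resample"))
  x <- as_nhwc(x)
  if (rs$i < rs$m) {
    k <- 2L^(rs$m - rs$i)
    if (dim(x)[1L] %% k != 0L || dim(x)[2L] %% k != 0L)
      stop("resample: spatial size not divisible by the pooling factor")
  }
  tp <- tg_tape(grad = FALSE)
  pn <- .param_nodes(rs$params)
  .resample_nodes(tp, tg_leaf(x), rs$i, rs$m, pn, "rs")$v
}
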