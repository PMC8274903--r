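#' Training configuration
#'
#' The published recipe: Adam (lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8),
#' batch 128 (DRIVE/CHASE_DB1; 512 for STARE), 200 epochs, seed 1234, 10000
#' dynamically sampled 48x48 patches (38000 for STARE), test-time overlap
#' stride 5, binarization threshold 0.47 (0.52 for STARE), geometric and
#' random-local-replacement augmentation, and step learning-rate decay.
#'
#' @param batch_size training batch size.
#' @param epochs training epochs.
#' @param lr initial learning rate.
#' @param adam_beta1,adam_beta2,adam_eps Adam moments/epsilon.
#' @param seed global seed for sampling/augmentation order.
#' @param n_patches dynamically sampled training patches.
#' @param stride test-time overlap sampling step.
#' @param patch_size patch side in pixels.
#' @param threshold probability binarization threshold.
#' @param lr_decay_factor,lr_decay_at decay multiplier and epoch fractions
#'   at which it applies (default x0.1 at 50% and 75% of the budget).
#' @param augment_geometric enable random flips and 90-degree rotations.
#' @param augment_local_replacement enable random local replacement
#'   (sub-window swaps between training pairs).
#' @param replace_prob,replace_window local-replacement probability and
#'   window-side range in px.
#' @param max_steps optional cap on optimizer steps for scaled-down runs;
#'   the decay schedule then compresses onto the actual step budget.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 128L, epochs = 200L, lr = 1e-3,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1234L,
                         n_patches = 10000L, stride = 5L, patch_size = 48L,
                         threshold = 0.47, lr_decay_factor = 0.1,
                         lr_decay_at = c(0.5, 0.75),
                         augment_geometric = TRUE,
                         augment_local_replacement = TRUE,
                         replace_prob = 0.5, replace_window = c(8L, 16L),
                         max_steps = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (any(c(batch_size, epochs, lr, n_patches, stride, patch_size) <= 0))
    stop("train_config: sizes and rates must be positive")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lr = lr, adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, seed = as.integer(seed),
                 n_patches = as.integer(n_patches), stride = as.integer(stride),
                 patch_size = as.integer(patch_size), threshold = threshold,
                 lr_decay_factor = lr_decay_factor, lr_decay_at = lr_decay_at,
                 augment_geometric = isTRUE(augment_geometric),
                 augment_local_replacement = isTRUE(augment_local_replacement),
                 replace_prob = replace_prob,
                 replace_window = as.integer(replace_window),
                 max_steps = if (is.null(max_steps)) NULL else as.integer(max_steps)),
            class = "train_config")
}

#' Dihedral transform of a patch
#'
#' One of the 8 axis-aligned symmetries: `rot` quarter-turns
#' (counter-clockwise) followed by an optional horizontal flip.
#'
#' @param x matrix.
#' @param rot 0-3 quarter turns.
#' @param flip flip horizontally after rotating.
#' @return transformed matrix.
#' @export
dihedral_transform <- function(x, rot = 0L, flip = FALSE) {
  rot <- rot %% 4L
  for (q in seq_len(rot)) x <- t(x)[nrow(t(x)):1, , drop = FALSE]
  if (flip) x <- x[, ncol(x):1, drop = FALSE]
  x
}

#' Geometric augmentation of an aligned image/mask pair
#'
#' Samples one of the 8 dihedral symmetries from the current RNG stream and
#' applies it identically to image and mask, so the pair stays pixel
#' aligned. With `geometric = FALSE` this is the identity.
#'
#' @param image,mask aligned matrices.
#' @param geometric enable the transform.
#' @return list `(image, mask)`.
#' @export
augment_pair <- function(image, mask, geometric = TRUE) {
  if (!geometric) return(list(image = image, mask = mask))
  rot <- sample.int(4L, 1L) - 1L
  flip <- stats::runif(1) < 0.5
  list(image = dihedral_transform(image, rot, flip),
       mask = dihedral_transform(mask, rot, flip))
}

#' Random local replacement between two training pairs
#'
#' Swaps a random square sub-window between two patches, applying the same
#' swap to the masks so image/mask alignment is preserved.
#'
#' @param img_a,msk_a,img_b,msk_b two aligned patch pairs.
#' @param window window-side range (sampled uniformly).
#' @return list of the two modified pairs.
#' @export
local_replacement <- function(img_a, msk_a, img_b, msk_b, window = c(8L, 16L)) {
  S <- nrow(img_a)
  w <- sample(window[1]:min(window[2], S), 1L)
  r0 <- sample.int(S - w + 1L, 1L)
  c0 <- sample.int(S - w + 1L, 1L)
  rows <- r0:(r0 + w - 1L); cols <- c0:(c0 + w - 1L)
  ia <- img_a[rows, cols]; ma <- msk_a[rows, cols]
  img_a[rows, cols] <- img_b[rows, cols]; msk_a[rows, cols] <- msk_b[rows, cols]
  img_b[rows, cols] <- ia; msk_b[rows, cols] <- ma
  list(img_a = img_a, msk_a = msk_a, img_b = img_b, msk_b = msk_b)
}

#' Step-decay learning-rate schedule
#'
#' Starts at `config$lr` and multiplies by `lr_decay_factor` at the epochs
#' given by `lr_decay_at` fractions of the budget; monotone non-increasing.
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  bounds <- floor(config$lr_decay_at * config$epochs)
  config$lr * config$lr_decay_factor^(vapply(epoch, function(e)
    sum(e >= bounds), 0))
}

#' Leave-one-out folds
#'
#' @param k dataset size (or a list whose length is used).
#' @return list of `k` folds, each `list(train = indices, test = j)`.
#' @export
leave_one_out_split <- function(k) {
  if (is.list(k)) k <- length(k)
  k <- as.integer(k)
  if (k < 2L) stop("leave_one_out_split: need at least 2 samples")
  lapply(seq_len(k), function(j) list(train = setdiff(seq_len(k), j), test = j))
}

.adam_init <- function(params) {
  zero_like <- function(a) {
    a[] <- 0
    a
  }
  list(m = lapply(params, zero_like),
       v = lapply(params, zero_like),
       t = 0L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.adam_step <- function(params, grads, opt, lr, b1, b2, eps) {
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a network on patches
#'
#' Minimizes per-pixel two-class softmax cross-entropy with Adam under the
#' configured schedule and augmentation. Fully reproducible: the seed fixes
#' batch order and augmentation draws (weights are fixed by the seed given
#' to [build_mfinet()]).
#'
#' @param model a built `mfinet_model` (not modified; a trained copy is
#'   returned).
#' @param patches `[S,S,n]` image patches, intensities in `[0, 255]` or
#'   `[0, 1]` (scaled internally to `[0, 1]`).
#' @param masks `[S,S,n]` binary vessel masks aligned with `patches`.
#' @param config a [train_config()].
#' @param verbose print the loss every 50 steps.
#' @return the trained model with a `history` data frame (step, epoch, lr,
#'   loss).
#' @export
train_mfinet <- function(model, patches, masks, config = train_config(),
                         verbose = FALSE) {
  stopifnot(inherits(model, "mfinet_model"), inherits(config, "train_config"))
  model <- .clone_model(model)
  n <- dim(patches)[3]
  if (max(patches) > 1) patches <- patches / 255
  set.seed(config$seed)
  steps_per_epoch <- max(1L, ceiling(n / config$batch_size))
  n_steps <- if (!is.null(config$max_steps)) config$max_steps
             else config$epochs * steps_per_epoch
  sched_cfg <- config
  sched_cfg$epochs <- max(1L, ceiling(n_steps / steps_per_epoch))
  opt <- .adam_init(model$params)
  S <- dim(patches)[1]
  hist <- data.frame(step = integer(n_steps), epoch = integer(n_steps),
                     lr = numeric(n_steps), loss = numeric(n_steps))
  for (step in seq_len(n_steps)) {
    epoch <- (step - 1L) %/% steps_per_epoch
    lr <- lr_schedule(epoch, sched_cfg)
    bs <- min(config$batch_size, n)
    idx <- sample.int(n, bs, replace = FALSE)
    xb <- array(0, c(S, S, 1L, bs))
    yb <- array(0, c(S, S, bs))
    for (q in seq_len(bs)) {
      pr <- augment_pair(patches[, , idx[q]], masks[, , idx[q]],
                         config$augment_geometric)
      xb[, , 1L, q] <- pr$image
      yb[, , q] <- pr$mask
    }
    if (config$augment_local_replacement && bs >= 2L) {
      pairs <- matrix(sample.int(bs), ncol = 2L)
      for (r in seq_len(nrow(pairs))) {
        if (stats::runif(1) >= config$replace_prob) next
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        sw <- local_replacement(xb[, , 1L, a], yb[, , a],
                                xb[, , 1L, b], yb[, , b],
                                config$replace_window)
        xb[, , 1L, a] <- sw$img_a; yb[, , a] <- sw$msk_a
        xb[, , 1L, b] <- sw$img_b; yb[, , b] <- sw$msk_b
      }
    }
    tp <- tg_tape(grad = TRUE)
    pn <- .param_nodes(model$params)
    out <- .forward_net(tp, model, pn, tg_leaf(xb), train = TRUE)
    loss <- op_softmax_ce(tp, out$logits, yb)
    if (!is.finite(loss$v))
      stop(sprintf("training diverged (non-finite loss) at step %d (epoch %d)",
                   step, epoch))
    tg_backward(tp, loss)
    grads <- lapply(pn, function(nd) nd$g)
    upd <- .adam_step(model$params, grads, opt, lr,
                      config$adam_beta1, config$adam_beta2, config$adam_eps)
    model$params <- upd$params
    opt <- upd$opt
    hist[step, ] <- list(step, epoch, lr, loss$v)
    if (verbose && (step %% 50L == 0L || step == 1L))
      message(sprintf("step %d/%d epoch %d lr %.2g loss %.4f",
                      step, n_steps, epoch, lr, loss$v))
  }
  model$opt <- opt
  model$history <- hist
  model
}

#' Segment one fundus sample
#'
#' Preprocesses the image, extracts the overlapping patch grid, runs the
#' network, reconstructs the full-size vessel probability map by overlap
#' averaging, and thresholds it inside the FOV.
#'
#' @param model trained `mfinet_model`.
#' @param sample a `fundus_sample` (RGB image + fov; `vessel` unused here).
#' @param config a [train_config()] (patch size, stride, threshold).
#' @param pre_config a [preprocess_config()].
#' @param batch patches per forward pass.
#' @return list with `prob` (full-size probability map) and `pred` (binary
#'   mask inside the FOV).
#' @export
predict_sample <- function(model, sample, config = train_config(),
                           pre_config = preprocess_config(), batch = 32L) {
  g <- preprocess_image(sample$image, pre_config) / 255
  pad <- pad_to_grid(g, config$patch_size, config$stride)
  ps <- extract_grid_patches(pad, source_id = sample$id)
  n <- dim(ps$patches)[3]
  probs <- array(0, dim(ps$patches))
  S <- config$patch_size
  for (q0 in seq(1L, n, by = batch)) {
    q1 <- min(q0 + batch - 1L, n)
    xb <- array(ps$patches[, , q0:q1], c(S, S, 1L, q1 - q0 + 1L))
    p <- mfinet_forward(model, xb, train = FALSE)
    probs[, , q0:q1] <- p[, , 2L, ]
  }
  ps$patches <- probs
  prob <- reconstruct_from_patches(ps)
  list(prob = prob,
       pred = binarize_probmap(prob, config$threshold, sample$fov))
}
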