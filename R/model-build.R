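# Parameter construction. All weights use the uniform fan-in rule
# U(-1/sqrt(fan_in), 1/sqrt(fan_in)) (the framework-default convolution
# initialization the training recipe calls for); batch-norm scales start at
# 1 and shifts at 0. Creation order is fixed, so a seed makes the full
# weight set reproducible.

.mk_conv <- function(B, name, kh, kw, cin, cout) {
  fan <- kh * kw * cin
  bnd <- sqrt(1 / fan)
  B$p[[paste0(name, ".w")]] <- array(stats::runif(kh * kw * cin * cout, -bnd, bnd),
                                     c(kh, kw, cin, cout))
  B$p[[paste0(name, ".b")]] <- stats::runif(cout, -bnd, bnd)
  invisible(NULL)
}

.mk_convT <- function(B, name, k, cin, cout) {
  fan <- k * k * cin
  bnd <- sqrt(1 / fan)
  B$p[[paste0(name, ".w")]] <- array(stats::runif(k * k * cin * cout, -bnd, bnd),
                                     c(k, k, cin, cout))
  B$p[[paste0(name, ".b")]] <- stats::runif(cout, -bnd, bnd)
  invisible(NULL)
}

.mk_bn <- function(B, name, C) {
  B$p[[paste0(name, ".g")]] <- rep(1, C)
  B$p[[paste0(name, ".be")]] <- rep(0, C)
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, C)
  st$running_var <- rep(1, C)
  B$s[[name]] <- st
  invisible(NULL)
}

.mk_dense <- function(B, name, dout, din) {
  bnd <- sqrt(1 / din)
  B$p[[paste0(name, ".w")]] <- matrix(stats::runif(dout * din, -bnd, bnd), dout, din)
  B$p[[paste0(name, ".b")]] <- stats::runif(dout, -bnd, bnd)
  invisible(NULL)
}

.mk_block <- function(B, name, cin, cout, residual) {
  .mk_conv(B, paste0(name, ".c1"), 3L, 3L, cin, cout)
  .mk_bn(B, paste0(name, ".bn1"), cout)
  .mk_conv(B, paste0(name, ".c2"), 3L, 3L, cout, cout)
  .mk_bn(B, paste0(name, ".bn2"), cout)
  if (residual && cin != cout) .mk_conv(B, paste0(name, ".proj"), 1L, 1L, cin, cout)
  invisible(NULL)
}

.mk_sa <- function(B, name, k) .mk_conv(B, name, k, k, 2L, 1L)

.mk_ca <- function(B, name, C, red) {
  h <- max(1L, C %/% red)
  .mk_dense(B, paste0(name, ".fc1"), h, C)
  .mk_dense(B, paste0(name, ".fc2"), C, h)
  invisible(NULL)
}

.mk_resample <- function(B, name, i, m, ci, cm) {
  if (i < m) .mk_conv(B, name, 3L, 3L, ci, cm)
  else if (i > m) .mk_convT(B, name, 2L^(i - m), ci, cm)
  invisible(NULL)
}

.enc_in_channels <- function(cfg, m) {
  if (m == 1L) return(if (cfg$use_mr) cfg$mr_widths[1L] else 1L)
  cfg$widths[m - 1L] +
    (if (cfg$use_mr) cfg$mr_widths[m] else 0L) +
    (if (cfg$use_mi) 1L else 0L)
}

#' Build a network from a configuration
#'
#' Allocates and initializes every trainable parameter of the configured
#' architecture. With a seed, two builds are bit-identical.
#'
#' @param config an [model_config()] object.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `mfinet_model` (config + named parameter list
#'   + batch-norm state).
#' @export
build_mfinet <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "mfinet_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- config
  B <- new.env(parent = emptyenv())
  B$p <- list()
  B$s <- list()
  w <- cfg$widths
  cm <- cfg$mr_widths
  red <- cfg$attn_reduction
  sk <- cfg$spatial_kernel

  if (cfg$use_mr) {
    .mk_conv(B, "stem", 3L, 3L, 1L, cm[1L])
    .mk_bn(B, "stem.bn", cm[1L])
    for (s in seq_len(cfg$mr_stages)) {
      for (m in seq_len(s)) {
        base <- paste0("mr.s", s, ".f", m)
        for (i in seq_len(s)) .mk_resample(B, paste0(base, ".r", i), i, m, cm[i], cm[m])
        for (i in seq_len(s)) .mk_sa(B, paste0(base, ".sa", i), sk)
        .mk_ca(B, paste0(base, ".ca"), cm[m], red)
      }
      base <- paste0("mr.s", s, ".gen")
      for (i in seq_len(s)) .mk_conv(B, paste0(base, ".r", i), 3L, 3L, cm[i], cm[s + 1L])
      for (i in seq_len(s)) .mk_sa(B, paste0(base, ".sa", i), sk)
      .mk_ca(B, paste0(base, ".ca"), cm[s + 1L], red)
    }
  }
  for (m in seq_len(cfg$n_levels))
    .mk_block(B, paste0("enc", m), .enc_in_channels(cfg, m), w[m], cfg$use_residual)
  for (m in seq.int(cfg$n_levels - 1L, 1L)) {
    .mk_convT(B, paste0("up", m), 2L, w[m + 1L], w[m])
    .mk_block(B, paste0("dec", m), 2L * w[m], w[m], cfg$use_residual)
  }
  if (cfg$use_fas) {
    for (m in seq_len(cfg$n_levels - 1L)) {
      base <- paste0("fas.m", m)
      for (i in seq_len(cfg$n_levels))
        .mk_resample(B, paste0(base, ".r", i), i, m, w[i], w[m])
      .mk_ca(B, paste0(base, ".ca"), w[m], red)
    }
  }
  .mk_conv(B, "head", 1L, 1L, w[1L], cfg$n_classes)

  model <- list(config = cfg, params = B$p, bn = B$s)
  class(model) <- "mfinet_model"
  model
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and dense weights and
#' biases, batch-norm scales and shifts; running statistics excluded).
#'
#' @param model an `mfinet_model`.
#' @return integer count; `print()` additionally shows it rounded to 0.1M.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mfinet_model"))
  sum(vapply(model$params, length, 0L))
}

#' @export
print.mfinet_model <- function(x, ...) {
  n <- count_parameters(x)
  cat("mfinet_model:", length(x$params), "parameter tensors,",
      n, sprintf("trainable parameters (%.1fM)\n", n / 1e6))
  print(x$config)
  invisible(x)
}

# deep copy (batch-norm states are environments)
.clone_model <- function(model) {
  bn <- lapply(model$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- st$running_mean
    e$running_var <- st$running_var
    e
  })
  out <- list(config = model$config, params = model$params, bn = bn,
              opt = model$opt, history = model$history)
  class(out) <- "mfinet_model"
  out
}
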