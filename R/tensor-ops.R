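# Reverse-mode autodiff tape over [H, W, C, N] arrays.
#
# Nodes are environments holding a value (`v`) and an accumulated gradient
# (`g`). Ops append nodes to the tape in creation order, which is a valid
# topological order, so backward() just walks the tape in reverse. Parameter
# leaves are created with tg_leaf() and collect gradients without being on
# the tape themselves.

tg_tape <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$k <- 0L
  tp$grad <- isTRUE(grad)
  tp
}

tg_leaf <- function(v) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd
}

tg_node <- function(tp, v, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  if (tp$grad && !is.null(bw)) {
    nd$bw <- bw
    tp$k <- tp$k + 1L
    if (tp$k > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$k]] <- nd
  }
  nd
}

tg_accum <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

tg_backward <- function(tp, loss) {
  stopifnot(length(loss$v) == 1L)
  loss$g <- 1
  if (tp$k > 0L) {
    for (q in tp$k:1L) {
      nd <- tp$nodes[[q]]
      if (!is.null(nd$g)) nd$bw(nd$g)
    }
  }
  invisible(NULL)
}

tg_dims <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a dim-ed array")
  d
}

# promote [H,W] or [H,W,C] to [H,W,C,N]
as_nhwc <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

## ---- convolution / pooling ----

op_conv <- function(tp, x, w, b, pad, reflect = FALSE) {
  v <- .cpp_conv2d_fwd(x$v, w$v, b$v, as.integer(pad), isTRUE(reflect))
  tg_node(tp, v, bw = function(g) {
    gr <- .cpp_conv2d_bwd(x$v, w$v, g, as.integer(pad), isTRUE(reflect))
    tg_accum(x, gr$dx); tg_accum(w, gr$dw); tg_accum(b, gr$db)
  })
}

op_convT <- function(tp, x, w, b, stride) {
  v <- .cpp_convT_fwd(x$v, w$v, b$v, as.integer(stride))
  tg_node(tp, v, bw = function(g) {
    gr <- .cpp_convT_bwd(x$v, w$v, g, as.integer(stride))
    tg_accum(x, gr$dx); tg_accum(w, gr$dw); tg_accum(b, gr$db)
  })
}

op_maxpool <- function(tp, x, k) {
  r <- .cpp_maxpool_fwd(x$v, as.integer(k))
  xd <- dim(x$v)
  tg_node(tp, r$y, bw = function(g) {
    tg_accum(x, .cpp_maxpool_bwd(r$idx, g, as.integer(xd)))
  })
}

## ---- elementwise ----

op_relu <- function(tp, x) {
  v <- .cpp_relu_fwd(x$v)
  tg_node(tp, v, bw = function(g) tg_accum(x, .cpp_relu_bwd(v, g)))
}

op_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-x$v))
  tg_node(tp, s, bw = function(g) tg_accum(x, g * s * (1 - s)))
}

op_add <- function(tp, ...) {
  xs <- list(...)
  v <- xs[[1L]]$v
  if (length(xs) > 1L) for (q in 2L:length(xs)) v <- v + xs[[q]]$v
  tg_node(tp, v, bw = function(g) for (x in xs) tg_accum(x, g))
}

# x: [H,W,C,N]; gate: [H,W,1,N] (spatial) or [1,1,C,N] (channel)
op_mul_gate <- function(tp, x, gate) {
  d <- tg_dims(x$v)
  gd <- tg_dims(gate$v)
  spatial <- gd[3] == 1L && gd[1] == d[1]
  v <- .cpp_bcast_mul(x$v, gate$v, spatial)
  tg_node(tp, v, bw = function(g) {
    tg_accum(x, .cpp_bcast_mul(g, gate$v, spatial))
    a <- g * x$v
    dg <- if (spatial) .cpp_reduce_c(a) else .cpp_reduce_hw(a)
    tg_accum(gate, dg)
  })
}

op_concat_c <- function(tp, xs) {
  d1 <- tg_dims(xs[[1L]]$v)
  cs <- vapply(xs, function(x) tg_dims(x$v)[3L], 0)
  Ctot <- sum(cs)
  v <- array(0, c(d1[1], d1[2], Ctot, d1[4]))
  off <- 0L
  for (x in xs) {
    ci <- tg_dims(x$v)[3L]
    v[, , (off + 1L):(off + ci), ] <- x$v
    off <- off + ci
  }
  tg_node(tp, v, bw = function(g) {
    off <- 0L
    for (x in xs) {
      ci <- tg_dims(x$v)[3L]
      tg_accum(x, g[, , (off + 1L):(off + ci), , drop = FALSE])
      off <- off + ci
    }
  })
}

## ---- batch normalization ----

# gamma/beta: length-C leaves; state: env with running_mean / running_var
op_bn <- function(tp, x, gamma, beta, state, train, momentum = 0.1, eps = 1e-5) {
  d <- tg_dims(x$v)
  C <- d[3]
  M <- d[1] * d[2] * d[4]
  zc <- numeric(C)
  if (train) {
    mu <- .cpp_sum_per_channel(x$v) / M
    xc <- .cpp_scale_shift_c(x$v, rep(1, C), -mu)
    var_ <- .cpp_sum_per_channel(xc * xc) / M
    inv <- 1 / sqrt(var_ + eps)
    xhat <- .cpp_scale_shift_c(xc, inv, zc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    ub <- if (M > 1) var_ * M / (M - 1) else var_
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
    v <- .cpp_scale_shift_c(xhat, gamma$v, beta$v)
    tg_node(tp, v, bw = function(g) {
      tg_accum(gamma, .cpp_sum_per_channel(g * xhat))
      tg_accum(beta, .cpp_sum_per_channel(g))
      # dxhat = g * gamma[c]; dx = inv/M * (M dxhat - sum(dxhat) - xhat sum(dxhat xhat))
      dxhat <- .cpp_scale_shift_c(g, gamma$v, zc)
      s1 <- .cpp_sum_per_channel(dxhat)
      s2 <- .cpp_sum_per_channel(dxhat * xhat)
      dx <- .cpp_lincomb_c(dxhat, xhat, inv, -inv * s2 / M, -inv * s1 / M)
      tg_accum(x, dx)
    })
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    xhat <- .cpp_scale_shift_c(x$v, inv, -state$running_mean * inv)
    v <- .cpp_scale_shift_c(xhat, gamma$v, beta$v)
    tg_node(tp, v, bw = function(g) {
      tg_accum(gamma, .cpp_sum_per_channel(g * xhat))
      tg_accum(beta, .cpp_sum_per_channel(g))
      tg_accum(x, .cpp_scale_shift_c(g, gamma$v * inv, zc))
    })
  }
}

## ---- global pooling and dense (channel attention MLP) ----

# global average pool -> [C, N]
op_gap <- function(tp, x) {
  d <- tg_dims(x$v)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- x$v
  dim(m) <- c(H * W, C * N)
  v <- matrix(colSums(m) / (H * W), C, N)
  tg_node(tp, v, bw = function(g) {
    dx <- array(rep(as.vector(g), each = H * W) / (H * W), d)
    tg_accum(x, dx)
  })
}

# global max pool -> [C, N]
op_gmp <- function(tp, x) {
  d <- tg_dims(x$v)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- x$v
  dim(m) <- c(H * W, C * N)
  arg <- max.col(t(m), ties.method = "first")  # per column of m
  v <- matrix(m[cbind(arg, seq_len(C * N))], C, N)
  tg_node(tp, v, bw = function(g) {
    dx <- numeric(length(x$v))
    pos <- arg + (seq_len(C * N) - 1L) * (H * W)
    dx[pos] <- as.vector(g)
    dim(dx) <- d
    tg_accum(x, dx)
  })
}

# dense layer on [in, N] matrices: v = W x + b
op_dense <- function(tp, x, w, b) {
  v <- w$v %*% x$v + b$v
  tg_node(tp, v, bw = function(g) {
    tg_accum(w, g %*% t(x$v))
    tg_accum(b, rowSums(g))
    tg_accum(x, t(w$v) %*% g)
  })
}

# reshape a [C, N] gate into a [1,1,C,N] tensor
op_as_cgate <- function(tp, x) {
  d <- tg_dims(x$v)
  v <- x$v
  dim(v) <- c(1L, 1L, d[1], d[2])
  tg_node(tp, v, bw = function(g) {
    dim(g) <- d
    tg_accum(x, g)
  })
}

# channel-wise mean and max across C -> [H,W,2,N] (spatial-attention input)
op_chan_mean_max <- function(tp, x) {
  r <- .cpp_cmeanmax_fwd(x$v)
  xd <- dim(x$v)
  tg_node(tp, r$y, bw = function(g) {
    tg_accum(x, .cpp_cmeanmax_bwd(r$arg, g, as.integer(xd)))
  })
}

## ---- softmax head ----

# channel softmax over C (inference probabilities)
op_softmax_c <- function(tp, x) {
  d <- tg_dims(x$v)
  ch <- function(a, c_) a[, , c_, , drop = FALSE]
  mx <- ch(x$v, 1L)
  if (d[3] > 1L) for (c_ in 2:d[3]) mx <- pmax(mx, ch(x$v, c_))
  e <- array(0, d)
  for (c_ in seq_len(d[3])) e[, , c_, ] <- exp(ch(x$v, c_) - mx)
  s <- ch(e, 1L)
  if (d[3] > 1L) for (c_ in 2:d[3]) s <- s + ch(e, c_)
  p <- array(0, d)
  for (c_ in seq_len(d[3])) p[, , c_, ] <- ch(e, c_) / s
  tg_node(tp, p, bw = function(g) {
    dot <- ch(g, 1L) * ch(p, 1L)
    if (d[3] > 1L) for (c_ in 2:d[3]) dot <- dot + ch(g, c_) * ch(p, c_)
    dx <- array(0, d)
    for (c_ in seq_len(d[3])) dx[, , c_, ] <- ch(p, c_) * (ch(g, c_) - dot)
    tg_accum(x, dx)
  })
}

# fused per-pixel softmax cross-entropy; target: [H,W,N] in {0,1},
# class 1 (vessel) is channel 2 of the logits
op_softmax_ce <- function(tp, logits, target) {
  d <- tg_dims(logits$v)
  stopifnot(d[3] == 2L)
  z1 <- logits$v[, , 1L, , drop = FALSE]
  z2 <- logits$v[, , 2L, , drop = FALSE]
  dim(z1) <- dim(z2) <- c(d[1], d[2], d[4])
  mx <- pmax(z1, z2)
  lse <- mx + log(exp(z1 - mx) + exp(z2 - mx))
  zt <- ifelse(target > 0.5, z2, z1)
  npix <- length(zt)
  loss <- sum(lse - zt) / npix
  p2 <- exp(z2 - lse)
  tg_node(tp, loss, bw = function(g) {
    t2 <- as.numeric(target > 0.5)
    d2 <- (p2 - t2) * (g / npix)
    dl <- array(0, d)
    dl[, , 1L, ] <- -d2
    dl[, , 2L, ] <- d2
    tg_accum(logits, dl)
  })
}
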