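# Minimal reverse-mode tape engine over 4-d (H, W, C, N) tensors.
# Every op appends a node to the tape; ag_backward() walks the tape in
# reverse, calling each node's `bw` closure and accumulating parent grads.
# All heavy lifting (conv/pool) is in src/nn_ops.cpp; the rest is plain R.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 512L)
  e$n <- 0L
  e
}

ag_emit <- function(tape, val, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$bw <- bw
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, val) ag_emit(tape, val)

ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (is.null(gs[[j]])) next
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL  # free intermediate grads eagerly
  }
  invisible(NULL)
}

# per-channel sums of a (H, W, C, N) tensor -> length-C vector
chan_sum <- function(x, d) {
  dim(x) <- d
  cpp_chan_stats(x)[, 1]
}

ag_conv <- function(tape, x, w, b, kh, kw, stride = 1L, pad = 0L) {
  y <- cpp_conv_fwd(x$val, w$val, b$val, kh, kw, stride, pad)
  ag_emit(tape, y, list(x, w, b), function(g) {
    gr <- cpp_conv_bwd(x$val, g, w$val, kh, kw, stride, pad)
    list(gr$dx, gr$dw, as.numeric(gr$db))
  })
}

# transposed convolution: weight kept in conv orientation
# (kh*kw*Cout, Cin); forward is the conv data-adjoint, so a stride-2 2x2
# kernel exactly doubles H and W.
ag_convt <- function(tape, x, w, b, kh, kw, stride = 2L) {
  d <- dim(x$val)
  H2 <- (d[1] - 1L) * stride + kh
  W2 <- (d[2] - 1L) * stride + kw
  y <- cpp_conv_bwd_data(x$val, w$val, kh, kw, stride, 0L, H2, W2)
  dy <- dim(y)
  y <- cpp_chan_affine(y, rep(1, length(b$val)), b$val)
  ag_emit(tape, y, list(x, w, b), function(g) {
    dim(g) <- dy
    list(cpp_conv_fwd(g, w$val, numeric(ncol(w$val)), kh, kw, stride, 0L),
         cpp_conv_bwd_filter(g, x$val, kh, kw, stride, 0L),
         chan_sum(g, dy))
  })
}

ag_maxpool <- function(tape, x, k, stride, pad = 0L) {
  r <- cpp_maxpool_fwd(x$val, k, stride, pad)
  xd <- dim(x$val)
  ag_emit(tape, r$y, list(x), function(g) {
    list(cpp_maxpool_bwd(g, r$idx, xd))
  })
}

ag_relu <- function(tape, x) {
  pos <- x$val > 0
  y <- x$val * pos
  ag_emit(tape, y, list(x), function(g) list(g * pos))
}

ag_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$val))
  ag_emit(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

ag_add <- function(tape, a, b) {
  ag_emit(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

# x: (H, W, C, N); w: (1, 1, C, N) per-channel-and-sample weights
ag_cmul <- function(tape, x, w) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  wexp <- rep(as.numeric(w$val), each = hw)
  y <- x$val * wexp
  dim(y) <- d
  ag_emit(tape, y, list(x, w), function(g) {
    dx <- g * wexp
    dim(dx) <- d
    m <- g * x$val
    dim(m) <- c(hw, d[3] * d[4])
    dw <- .colSums(m, hw, d[3] * d[4])
    dim(dw) <- c(1L, 1L, d[3], d[4])
    list(dx, dw)
  })
}

ag_concat <- function(tape, a, b) {
  da <- dim(a$val)
  out <- cpp_concat(a$val, b$val)
  ag_emit(tape, out, list(a, b), function(g) {
    dim(g) <- dim(out)
    sp <- cpp_split_channels(g, da[3])
    list(sp$a, sp$b)
  })
}

# global average pooling -> (1, 1, C, N)
ag_gap <- function(tape, x) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  m <- x$val
  dim(m) <- c(hw, d[3] * d[4])
  y <- .colSums(m, hw, d[3] * d[4]) / hw
  dim(y) <- c(1L, 1L, d[3], d[4])
  ag_emit(tape, y, list(x), function(g) {
    dx <- rep(as.numeric(g) / hw, each = hw)
    dim(dx) <- d
    list(dx)
  })
}

# batch normalization over (H, W, N) per channel; `rs` is an environment
# holding running mean/var, updated as a side effect in training mode
ag_bn <- function(tape, x, gamma, beta, rs, training, momentum = 0.1,
                  eps = 1e-5) {
  d <- dim(x$val)
  m <- d[1] * d[2] * d[4]
  if (training) {
    st <- cpp_chan_stats(x$val)
    mu <- st[, 1] / m
    v <- pmax(st[, 2] / m - mu^2, 0)
    rs$mean <- (1 - momentum) * rs$mean + momentum * mu
    rs$var <- (1 - momentum) * rs$var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- rs$mean
    v <- rs$var
  }
  istd <- 1 / sqrt(v + eps)
  sc <- gamma$val * istd
  y <- cpp_chan_affine(x$val, sc, beta$val - sc * mu)
  ag_emit(tape, y, list(x, gamma, beta), function(g) {
    dim(g) <- d
    r <- cpp_bn_bwd(g, x$val, mu, istd, gamma$val, training)
    list(r$dx, r$dgamma, r$dbeta)
  })
}

# soft-Dice + binary cross-entropy on foreground logits (H, W, 1, N)
ag_dice_bce <- function(tape, logits, target, w_dice = 1, w_bce = 1,
                        eps = 1) {
  d <- dim(logits$val)
  n <- d[4]
  hw <- d[1] * d[2] * d[3]
  p <- 1 / (1 + exp(-logits$val))
  pm <- p; dim(pm) <- c(hw, n)
  tm <- target; dim(tm) <- c(hw, n)
  inter <- .colSums(pm * tm, hw, n)
  sums <- .colSums(pm, hw, n) + .colSums(tm, hw, n)
  dice <- (2 * inter + eps) / (sums + eps)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(pc) + (1 - target) * log(1 - pc))
  loss <- w_dice * mean(1 - dice) + w_bce * bce
  ag_emit(tape, loss, list(logits), function(g) {
    # d(1 - dice_i)/dp_j = -(2 t_j (sums_i + eps) - (2 inter_i + eps)) / (sums_i + eps)^2
    a <- rep(2 / (sums + eps), each = hw)
    b <- rep((2 * inter + eps) / (sums + eps)^2, each = hw)
    ddice_dp <- -(a * target - b)
    dl_dp <- w_dice * ddice_dp / n
    dl_dz_dice <- dl_dp * p * (1 - p)
    dl_dz_bce <- w_bce * (p - target) / length(target)
    dz <- g * (dl_dz_dice + dl_dz_bce)
    dim(dz) <- d
    list(dz)
  })
}

# weighted softmax cross-entropy; logits (1, 1, K, N), y integer 1..K
ag_softmax_ce <- function(tape, logits, y, class_weights = NULL) {
  d <- dim(logits$val)
  K <- d[3]; n <- d[4]
  z <- logits$val
  dim(z) <- c(K, n)
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  if (is.null(class_weights)) class_weights <- rep(1, K)
  wy <- class_weights[y]
  iy <- cbind(y, seq_len(n))
  py <- p[cbind(y, seq_len(n))]
  loss <- sum(-wy * log(pmax(py, 1e-12))) / sum(wy)
  ag_emit(tape, loss, list(logits), function(g) {
    oh <- matrix(0, K, n)
    oh[iy] <- 1
    dz <- sweep(p - oh, 2, wy, "*") / sum(wy)
    dz <- g * dz
    dim(dz) <- d
    list(dz)
  })
}

softmax_probs <- function(logits) {
  d <- dim(logits)
  K <- d[3]; n <- d[4]
  z <- logits
  dim(z) <- c(K, n)
  z <- sweep(z, 2, apply(z, 2, max))
  ez <- exp(z)
  t(sweep(ez, 2, colSums(ez), "/"))
}
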