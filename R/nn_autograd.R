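# Minimal reverse-mode autodiff on channels-last feature maps.
#
# A feature map with N samples, spatial size H x W and C channels is stored
# as an (N*H*W) x C matrix whose rows are ordered x-fastest, then y, then
# sample: row = x + (y-1)*W + (n-1)*W*H. Every operation appends a node to a
# tape; backward() walks the tape in reverse, calling each node's pullback.
# This is deliberately small: only the operations the detector needs exist.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512)
  tp$k <- 0L
  tp
}

tape_node <- function(tp, val, H, W, C, N, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$H <- H; nd$W <- W; nd$C <- C; nd$N <- N
  nd$grad <- NULL
  nd$bw <- bw
  if (!is.null(tp)) {
    tp$k <- tp$k + 1L
    if (tp$k > length(tp$nodes)) length(tp$nodes) <- 2L * length(tp$nodes)
    tp$nodes[[tp$k]] <- nd
  }
  nd
}

nd_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

tape_backward <- function(tp, loss) {
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tp$k))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

# trainable parameter: a flat environment with value, gradient and Adam state
new_param <- function(dims, sd = NULL, init = NULL, decay = TRUE) {
  p <- new.env(parent = emptyenv())
  n <- prod(dims)
  if (is.null(init)) {
    init <- if (is.null(sd) || sd == 0) rep(0, n) else stats::rnorm(n, 0, sd)
  }
  p$val <- array(init, dim = dims)
  p$grad <- array(0, dim = dims)
  p$decay <- decay
  p$m <- NULL; p$v <- NULL
  class(p) <- "nn_param"
  p
}

param_size <- function(p) length(p$val)

# ---- tensor packing --------------------------------------------------------

# list of H x W x 3 rasters -> input node (values scaled to [0, 1])
images_to_node <- function(tp, imgs) {
  h <- dim(imgs[[1]])[1]; w <- dim(imgs[[1]])[2]
  n <- length(imgs)
  val <- matrix(0, n * h * w, 3)
  for (i in seq_len(n)) {
    im <- imgs[[i]] / 255
    rows <- (i - 1) * h * w + seq_len(h * w)
    # row-major within sample (x fastest): transpose each channel plane
    for (k in 1:3) val[rows, k] <- as.vector(t(im[, , k]))
  }
  tape_node(tp, val, H = h, W = w, C = 3L, N = n)
}

node_to_maps <- function(nd) {
  # back to a list (per sample) of H x W x C arrays
  lapply(seq_len(nd$N), function(i) {
    rows <- (i - 1) * nd$H * nd$W + seq_len(nd$H * nd$W)
    arr <- array(0, dim = c(nd$H, nd$W, nd$C))
    for (k in seq_len(nd$C)) {
      arr[, , k] <- matrix(nd$val[rows, k], nd$H, nd$W, byrow = TRUE)
    }
    arr
  })
}

# ---- convolution -----------------------------------------------------------

# Precompute gather indices for a k x k / stride-s / pad-p convolution over an
# H x W x N grid (cached per layer and input shape).
conv_index <- function(H, W, N, k, s, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  xo <- rep(seq_len(Wo), times = Ho * N)
  yo <- rep(rep(seq_len(Ho), each = Wo), times = N)
  nn <- rep(seq_len(N), each = Wo * Ho)
  offs <- vector("list", k * k)
  for (dy in 0:(k - 1L)) for (dx in 0:(k - 1L)) {
    xi <- (xo - 1L) * s + dx + 1L
    yi <- (yo - 1L) * s + dy + 1L
    offs[[dy * k + dx + 1L]] <- xi + (yi - 1L) * Wp + (nn - 1L) * Wp * Hp
  }
  xs <- rep(seq_len(W), times = H * N)
  ys <- rep(rep(seq_len(H), each = W), times = N)
  ns <- rep(seq_len(N), each = W * H)
  scatter <- (xs + p) + (ys + p - 1L) * Wp + (ns - 1L) * Wp * Hp
  list(Ho = Ho, Wo = Wo, offs = offs, scatter = scatter, np = Wp * Hp * N)
}

layer_conv_index <- function(layer, H, W, N, k, s, p) {
  key <- paste(H, W, N, sep = "x")
  ci <- layer$idx_cache[[key]]
  if (is.null(ci)) {
    ci <- conv_index(H, W, N, k, s, p)
    layer$idx_cache[[key]] <- ci
  }
  ci
}

# Dense convolution: weight param has dim (k*k*Cin, Cout).
op_conv <- function(tp, x, layer) {
  k <- layer$k; s <- layer$s; p <- layer$p
  ci <- layer_conv_index(layer, x$H, x$W, x$N, k, s, p)
  cin <- x$C
  Xp <- matrix(0, ci$np, cin)
  Xp[ci$scatter, ] <- x$val
  W <- layer$W$val
  cout <- ncol(W)
  out <- matrix(0, length(ci$offs[[1]]), cout)
  for (o in seq_along(ci$offs)) {
    rows <- (o - 1L) * cin + seq_len(cin)
    out <- out + Xp[ci$offs[[o]], , drop = FALSE] %*% W[rows, , drop = FALSE]
  }
  if (!is.null(layer$b)) out <- out + rep(layer$b$val, each = nrow(out))
  nd <- tape_node(tp, out, ci$Ho, ci$Wo, cout, x$N, bw = function(nd) {
    g <- nd$grad
    dXp <- matrix(0, ci$np, cin)
    dW <- layer$W$grad
    for (o in seq_along(ci$offs)) {
      rows <- (o - 1L) * cin + seq_len(cin)
      idx <- ci$offs[[o]]
      sub <- Xp[idx, , drop = FALSE]
      dW[rows, ] <- dW[rows, ] + crossprod(sub, g)
      dXp[idx, ] <- dXp[idx, , drop = FALSE] +
        g %*% t(W[rows, , drop = FALSE])
    }
    layer$W$grad <- dW
    if (!is.null(layer$b)) layer$b$grad <- layer$b$grad + colSums(g)
    nd_accum(x, dXp[ci$scatter, , drop = FALSE])
  })
  nd
}

# Depthwise convolution: weight param has dim (k*k, C).
op_conv_dw <- function(tp, x, layer) {
  k <- layer$k; s <- layer$s; p <- layer$p
  ci <- layer_conv_index(layer, x$H, x$W, x$N, k, s, p)
  C <- x$C
  Xp <- matrix(0, ci$np, C)
  Xp[ci$scatter, ] <- x$val
  W <- layer$W$val
  S_out <- length(ci$offs[[1]])
  out <- matrix(0, S_out, C)
  for (o in seq_along(ci$offs)) {
    out <- out + Xp[ci$offs[[o]], , drop = FALSE] *
      matrix(W[o, ], S_out, C, byrow = TRUE)
  }
  nd <- tape_node(tp, out, ci$Ho, ci$Wo, C, x$N, bw = function(nd) {
    g <- nd$grad
    dXp <- matrix(0, ci$np, C)
    dW <- layer$W$grad
    for (o in seq_along(ci$offs)) {
      idx <- ci$offs[[o]]
      sub <- Xp[idx, , drop = FALSE]
      dW[o, ] <- dW[o, ] + colSums(g * sub)
      dXp[idx, ] <- dXp[idx, , drop = FALSE] +
        g * matrix(W[o, ], S_out, C, byrow = TRUE)
    }
    layer$W$grad <- dW
    nd_accum(x, dXp[ci$scatter, , drop = FALSE])
  })
  nd
}

# ---- normalization and activations ----------------------------------------

op_bn <- function(tp, x, layer, training) {
  eps <- 1e-5
  if (training) {
    mu <- colMeans(x$val)
    xc <- x$val - rep(mu, each = nrow(x$val))
    va <- colMeans(xc * xc)
    mom <- 0.1
    layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
    layer$running_var <- (1 - mom) * layer$running_var + mom * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
    xc <- x$val - rep(mu, each = nrow(x$val))
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = nrow(xc))
  gma <- layer$gamma$val
  out <- xhat * rep(gma, each = nrow(xhat)) +
    rep(layer$beta$val, each = nrow(xhat))
  nd <- tape_node(tp, out, x$H, x$W, x$C, x$N, bw = function(nd) {
    g <- nd$grad
    S <- nrow(g)
    layer$gamma$grad <- layer$gamma$grad + colSums(g * xhat)
    layer$beta$grad <- layer$beta$grad + colSums(g)
    if (training) {
      mg <- colMeans(g)
      mgx <- colMeans(g * xhat)
      dx <- (g - rep(mg, each = S) - xhat * rep(mgx, each = S)) *
        rep(gma * inv, each = S)
    } else {
      dx <- g * rep(gma * inv, each = S)
    }
    nd_accum(x, dx)
  })
  nd
}

op_silu <- function(tp, x) {
  s <- 1 / (1 + exp(-x$val))
  out <- x$val * s
  nd <- tape_node(tp, out, x$H, x$W, x$C, x$N, bw = function(nd) {
    nd_accum(x, nd$grad * (s * (1 + x$val * (1 - s))))
  })
  nd
}

op_sigmoid <- function(tp, x) {
  s <- 1 / (1 + exp(-x$val))
  nd <- tape_node(tp, s, x$H, x$W, x$C, x$N, bw = function(nd) {
    nd_accum(x, nd$grad * s * (1 - s))
  })
  nd
}

op_add <- function(tp, a, b) {
  nd <- tape_node(tp, a$val + b$val, a$H, a$W, a$C, a$N, bw = function(nd) {
    nd_accum(a, nd$grad); nd_accum(b, nd$grad)
  })
  nd
}

op_concat_c <- function(tp, parts) {
  vals <- lapply(parts, function(p) p$val)
  out <- do.call(cbind, vals)
  cs <- cumsum(c(0L, vapply(parts, function(p) p$C, 0L)))
  nd <- tape_node(tp, out, parts[[1]]$H, parts[[1]]$W, ncol(out),
                  parts[[1]]$N, bw = function(nd) {
    for (i in seq_along(parts)) {
      nd_accum(parts[[i]], nd$grad[, (cs[i] + 1L):cs[i + 1L], drop = FALSE])
    }
  })
  nd
}

op_slice_c <- function(tp, x, cols) {
  nd <- tape_node(tp, x$val[, cols, drop = FALSE], x$H, x$W, length(cols),
                  x$N, bw = function(nd) {
    g <- matrix(0, nrow(x$val), x$C)
    g[, cols] <- nd$grad
    nd_accum(x, g)
  })
  nd
}

op_permute_c <- function(tp, x, perm) {
  inv <- order(perm)
  nd <- tape_node(tp, x$val[, perm, drop = FALSE], x$H, x$W, x$C, x$N,
                  bw = function(nd) nd_accum(x, nd$grad[, inv, drop = FALSE]))
  nd
}

# ---- pooling and resampling ------------------------------------------------

op_maxpool <- function(tp, x, layer) {
  k <- layer$k; s <- layer$s; p <- layer$p
  ci <- layer_conv_index(layer, x$H, x$W, x$N, k, s, p)
  C <- x$C
  Xp <- matrix(-Inf, ci$np, C)
  Xp[ci$scatter, ] <- x$val
  S_out <- length(ci$offs[[1]])
  cur <- Xp[ci$offs[[1]], , drop = FALSE]
  arg <- matrix(1L, S_out, C)
  for (o in 2:length(ci$offs)) {
    cand <- Xp[ci$offs[[o]], , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- o
  }
  nd <- tape_node(tp, cur, ci$Ho, ci$Wo, C, x$N, bw = function(nd) {
    g <- nd$grad
    dXp <- matrix(0, ci$np, C)
    for (o in seq_along(ci$offs)) {
      m <- arg == o
      if (!any(m)) next
      idx <- ci$offs[[o]]
      dXp[idx, ] <- dXp[idx, , drop = FALSE] + g * m
    }
    nd_accum(x, dXp[ci$scatter, , drop = FALSE])
  })
  nd
}

op_upsample2 <- function(tp, x) {
  H2 <- 2L * x$H; W2 <- 2L * x$W
  xo <- rep(seq_len(W2), times = H2 * x$N)
  yo <- rep(rep(seq_len(H2), each = W2), times = x$N)
  nn <- rep(seq_len(x$N), each = W2 * H2)
  src <- ((xo + 1L) %/% 2L) + (((yo + 1L) %/% 2L) - 1L) * x$W +
    (nn - 1L) * x$W * x$H
  nd <- tape_node(tp, x$val[src, , drop = FALSE], H2, W2, x$C, x$N,
                  bw = function(nd) {
    nd_accum(x, rowsum(nd$grad, src, reorder = TRUE))
  })
  nd
}

# per-sample global pools: output has H = W = 1 (one row per sample)
op_gap <- function(tp, x) {
  grp <- rep(seq_len(x$N), each = x$H * x$W)
  hw <- x$H * x$W
  out <- rowsum(x$val, grp, reorder = TRUE) / hw
  nd <- tape_node(tp, out, 1L, 1L, x$C, x$N, bw = function(nd) {
    nd_accum(x, nd$grad[grp, , drop = FALSE] / hw)
  })
  nd
}

op_gmp <- function(tp, x) {
  hw <- x$H * x$W
  out <- matrix(0, x$N, x$C)
  argr <- matrix(0L, x$N, x$C)
  for (i in seq_len(x$N)) {
    rows <- (i - 1L) * hw + seq_len(hw)
    blk <- x$val[rows, , drop = FALSE]
    am <- max.col(t(blk), ties.method = "first")
    out[i, ] <- blk[cbind(am, seq_len(x$C))]
    argr[i, ] <- rows[am]
  }
  nd <- tape_node(tp, out, 1L, 1L, x$C, x$N, bw = function(nd) {
    g <- matrix(0, nrow(x$val), x$C)
    ij <- cbind(as.vector(argr), rep(seq_len(x$C), each = x$N))
    g[ij] <- g[ij] + as.vector(nd$grad)
    nd_accum(x, g)
  })
  nd
}

# multiply a feature map by a per-sample channel gate (N x C node)
op_mul_channel_gate <- function(tp, x, gate) {
  grp <- rep(seq_len(x$N), each = x$H * x$W)
  G <- gate$val[grp, , drop = FALSE]
  nd <- tape_node(tp, x$val * G, x$H, x$W, x$C, x$N, bw = function(nd) {
    nd_accum(x, nd$grad * G)
    nd_accum(gate, rowsum(nd$grad * x$val, grp, reorder = TRUE))
  })
  nd
}

# multiply a feature map by a spatial gate (S x 1 node, same grid)
op_mul_spatial_gate <- function(tp, x, gate) {
  gv <- gate$val[, 1]
  nd <- tape_node(tp, x$val * gv, x$H, x$W, x$C, x$N, bw = function(nd) {
    nd_accum(x, nd$grad * gv)
    nd_accum(gate, matrix(rowSums(nd$grad * x$val), ncol = 1))
  })
  nd
}

# per-row channel mean and max, stacked as a 2-channel map (for CBAM)
op_chan_meanmax <- function(tp, x) {
  mu <- rowMeans(x$val)
  am <- max.col(x$val, ties.method = "first")
  mx <- x$val[cbind(seq_len(nrow(x$val)), am)]
  nd <- tape_node(tp, cbind(mu, mx), x$H, x$W, 2L, x$N, bw = function(nd) {
    g <- matrix(nd$grad[, 1] / x$C, nrow(x$val), x$C)
    ij <- cbind(seq_len(nrow(x$val)), am)
    g[ij] <- g[ij] + nd$grad[, 2]
    nd_accum(x, g)
  })
  nd
}

# dense layer on (N x C) gate descriptors: out = x W + b
op_dense <- function(tp, x, layer) {
  out <- x$val %*% layer$W$val
  if (!is.null(layer$b)) out <- out + rep(layer$b$val, each = nrow(out))
  nd <- tape_node(tp, out, x$H, x$W, ncol(out), x$N, bw = function(nd) {
    layer$W$grad <- layer$W$grad + crossprod(x$val, nd$grad)
    if (!is.null(layer$b)) layer$b$grad <- layer$b$grad + colSums(nd$grad)
    nd_accum(x, nd$grad %*% t(layer$W$val))
  })
  nd
}

# per-sample matmul over flattened spatial maps (for non-local attention):
# a is (N*H*W) x Ca, b is (N*H*W) x Cb; returns per sample A_n %*% t(B_n)
# (transpose_b) or A_n %*% B_n-stacked variants as needed.
op_matmul_persample <- function(tp, a, b, transpose_b = FALSE) {
  hw_a <- a$H * a$W; hw_b <- b$H * b$W
  outC <- if (transpose_b) hw_b else b$C
  out <- matrix(0, a$N * hw_a, outC)
  for (i in seq_len(a$N)) {
    ra <- (i - 1L) * hw_a + seq_len(hw_a)
    rb <- (i - 1L) * hw_b + seq_len(hw_b)
    A <- a$val[ra, , drop = FALSE]
    B <- b$val[rb, , drop = FALSE]
    out[ra, ] <- if (transpose_b) tcrossprod(A, B) else A %*% B
  }
  nd <- tape_node(tp, out, a$H, a$W, outC, a$N, bw = function(nd) {
    ga <- matrix(0, nrow(a$val), a$C)
    gb <- matrix(0, nrow(b$val), b$C)
    for (i in seq_len(a$N)) {
      ra <- (i - 1L) * hw_a + seq_len(hw_a)
      rb <- (i - 1L) * hw_b + seq_len(hw_b)
      G <- nd$grad[ra, , drop = FALSE]
      A <- a$val[ra, , drop = FALSE]
      B <- b$val[rb, , drop = FALSE]
      if (transpose_b) {
        ga[ra, ] <- G %*% B
        gb[rb, ] <- crossprod(G, A)
      } else {
        ga[ra, ] <- tcrossprod(G, B)
        gb[rb, ] <- crossprod(A, G)
      }
    }
    nd_accum(a, ga); nd_accum(b, gb)
  })
  nd
}

op_row_softmax <- function(tp, x) {
  z <- x$val - apply(x$val, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  nd <- tape_node(tp, p, x$H, x$W, x$C, x$N, bw = function(nd) {
    dot <- rowSums(nd$grad * p)
    nd_accum(x, p * (nd$grad - dot))
  })
  nd
}

op_scale_const <- function(tp, x, a, b = 0) {
  nd <- tape_node(tp, x$val * a + b, x$H, x$W, x$C, x$N,
                  bw = function(nd) nd_accum(x, nd$grad * a))
  nd
}

op_gather_rows <- function(tp, x, idx) {
  nd <- tape_node(tp, x$val[idx, , drop = FALSE], 1L, 1L, x$C, length(idx),
                  bw = function(nd) {
    g <- matrix(0, nrow(x$val), x$C)
    g[idx, ] <- nd$grad
    nd_accum(x, g)
  })
  nd
}
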