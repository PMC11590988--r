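# Elementwise tape operations used to build differentiable training losses.
# These act on small (P x k) matrices (one row per assigned anchor), so the
# per-op overhead is negligible compared with the network forward pass.

ew_node <- function(tp, val, like, bw) {
  tape_node(tp, val, like$H, like$W, ncol(val), like$N, bw = bw)
}

ew_add <- function(tp, a, b) {
  ew_node(tp, a$val + b$val, a, function(nd) {
    nd_accum(a, nd$grad); nd_accum(b, nd$grad)
  })
}

ew_sub <- function(tp, a, b) {
  ew_node(tp, a$val - b$val, a, function(nd) {
    nd_accum(a, nd$grad); nd_accum(b, -nd$grad)
  })
}

ew_mul <- function(tp, a, b) {
  ew_node(tp, a$val * b$val, a, function(nd) {
    nd_accum(a, nd$grad * b$val); nd_accum(b, nd$grad * a$val)
  })
}

ew_div <- function(tp, a, b) {
  ew_node(tp, a$val / b$val, a, function(nd) {
    nd_accum(a, nd$grad / b$val)
    nd_accum(b, -nd$grad * a$val / (b$val * b$val))
  })
}

ew_max2 <- function(tp, a, b) {
  m <- a$val >= b$val
  ew_node(tp, pmax(a$val, b$val), a, function(nd) {
    nd_accum(a, nd$grad * m); nd_accum(b, nd$grad * !m)
  })
}

ew_min2 <- function(tp, a, b) {
  m <- a$val <= b$val
  ew_node(tp, pmin(a$val, b$val), a, function(nd) {
    nd_accum(a, nd$grad * m); nd_accum(b, nd$grad * !m)
  })
}

ew_const <- function(tp, x, const) {  # constant matrix shaped like x
  tape_node(tp, matrix(const, nrow(x$val), ncol(x$val)), x$H, x$W,
            ncol(x$val), x$N)
}

ew_addc <- function(tp, x, c) {
  ew_node(tp, x$val + c, x, function(nd) nd_accum(x, nd$grad))
}

ew_mulc <- function(tp, x, c) {
  ew_node(tp, x$val * c, x, function(nd) nd_accum(x, nd$grad * c))
}

ew_clamp_min <- function(tp, x, lo) {
  m <- x$val > lo
  ew_node(tp, pmax(x$val, lo), x, function(nd) nd_accum(x, nd$grad * m))
}

ew_abs <- function(tp, x) {
  s <- sign(x$val)
  ew_node(tp, abs(x$val), x, function(nd) nd_accum(x, nd$grad * s))
}

ew_sqrt <- function(tp, x) {
  v <- sqrt(pmax(x$val, 1e-12))
  ew_node(tp, v, x, function(nd) nd_accum(x, nd$grad * 0.5 / v))
}

ew_pow <- function(tp, x, a) {  # x > 0 assumed
  base <- pmax(x$val, 1e-12)
  v <- base^a
  ew_node(tp, v, x, function(nd) nd_accum(x, nd$grad * a * base^(a - 1)))
}

ew_exp <- function(tp, x) {
  v <- exp(x$val)
  ew_node(tp, v, x, function(nd) nd_accum(x, nd$grad * v))
}

ew_atan <- function(tp, x) {
  ew_node(tp, atan(x$val), x, function(nd) {
    nd_accum(x, nd$grad / (1 + x$val * x$val))
  })
}

ew_col <- function(tp, x, j) {
  ew_node(tp, x$val[, j, drop = FALSE], x, function(nd) {
    g <- matrix(0, nrow(x$val), ncol(x$val))
    g[, j] <- nd$grad
    nd_accum(x, g)
  })
}

ew_mean <- function(tp, x) {
  n <- length(x$val)
  tape_node(tp, matrix(mean(x$val), 1, 1), 1L, 1L, 1L, 1L, bw = function(nd) {
    nd_accum(x, matrix(nd$grad[1] / n, nrow(x$val), ncol(x$val)))
  })
}

ew_weighted_sum_scalar <- function(tp, parts, weights) {
  v <- sum(vapply(seq_along(parts), function(i) weights[i] * parts[[i]]$val[1],
                  0))
  tape_node(tp, matrix(v, 1, 1), 1L, 1L, 1L, 1L, bw = function(nd) {
    for (i in seq_along(parts)) {
      nd_accum(parts[[i]], matrix(nd$grad[1] * weights[i], 1, 1))
    }
  })
}

# ---- composite loss heads --------------------------------------------------

# distribution focal loss head: logits (P x 4*reg_max) against continuous
# targets (P x 4) in bin units; mean weighted cross-entropy over P*4 sides
op_dfl_loss <- function(tp, logits, targets, reg_max) {
  P <- nrow(targets)
  t <- pmin(pmax(targets, 0), reg_max - 1 - 1e-6)
  l <- floor(t); r <- l + 1
  wl <- r - t; wr <- t - l
  # logits columns are side-major: side s occupies ((s-1)*reg_max+1):(s*reg_max)
  loss <- 0
  probs <- array(0, dim = c(P, reg_max, 4))
  for (s in 1:4) {
    cols <- (s - 1L) * reg_max + seq_len(reg_max)
    zz <- logits$val[, cols, drop = FALSE]
    zz <- zz - apply(zz, 1, max)
    e <- exp(zz)
    p <- e / rowSums(e)
    probs[, , s] <- p
    li <- cbind(seq_len(P), l[, s] + 1L)
    ri <- cbind(seq_len(P), pmin(r[, s] + 1L, reg_max))
    loss <- loss - sum(wl[, s] * log(pmax(p[li], 1e-12)) +
                         wr[, s] * log(pmax(p[ri], 1e-12)))
  }
  val <- loss / (4 * max(P, 1))
  tape_node(tp, matrix(val, 1, 1), 1L, 1L, 1L, 1L, bw = function(nd) {
    g <- matrix(0, P, 4L * reg_max)
    for (s in 1:4) {
      cols <- (s - 1L) * reg_max + seq_len(reg_max)
      q <- matrix(0, P, reg_max)
      q[cbind(seq_len(P), l[, s] + 1L)] <- wl[, s]
      ri <- cbind(seq_len(P), pmin(r[, s] + 1L, reg_max))
      q[ri] <- q[ri] + wr[, s]
      g[, cols] <- (probs[, , s] - q) / (4 * max(P, 1))
    }
    nd_accum(logits, nd$grad[1] * g)
  })
}

# mean binary cross-entropy with logits over an (S x nc) map
op_bce_loss <- function(tp, logits, targets) {
  z <- logits$val
  # numerically stable: log(1+exp(-|z|)) + max(z,0) - z*t
  loss <- mean(pmax(z, 0) - z * targets + log1p(exp(-abs(z))))
  n <- length(z)
  tape_node(tp, matrix(loss, 1, 1), 1L, 1L, 1L, 1L, bw = function(nd) {
    s <- 1 / (1 + exp(-z))
    nd_accum(logits, nd$grad[1] * (s - targets) / n)
  })
}

# expected bin value per side: logits (P x 4*reg_max) -> distances (P x 4)
op_dfl_expect <- function(tp, logits, reg_max) {
  P <- nrow(logits$val)
  out <- matrix(0, P, 4)
  probs <- vector("list", 4)
  bins <- 0:(reg_max - 1)
  for (s in 1:4) {
    cols <- (s - 1L) * reg_max + seq_len(reg_max)
    zz <- logits$val[, cols, drop = FALSE]
    zz <- zz - apply(zz, 1, max)
    e <- exp(zz)
    p <- e / rowSums(e)
    probs[[s]] <- p
    out[, s] <- p %*% bins
  }
  tape_node(tp, out, 1L, 1L, 4L, P, bw = function(nd) {
    g <- matrix(0, P, 4L * reg_max)
    for (s in 1:4) {
      cols <- (s - 1L) * reg_max + seq_len(reg_max)
      p <- probs[[s]]
      ev <- out[, s]
      # d E / d z_k = p_k (k - E)
      g[, cols] <- p * (matrix(bins, P, reg_max, byrow = TRUE) - ev) *
        nd$grad[, s]
    }
    nd_accum(logits, g)
  })
}
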