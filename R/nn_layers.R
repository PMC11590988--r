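# Layer and block constructors for the detector family. Each primitive layer
# is an environment holding its parameters (plus cached gather indices);
# composite blocks are plain tagged lists. Forward functions take the tape,
# the input node and a `training` flag.

nn_conv <- function(cin, cout, k = 1, s = 1, bias = FALSE) {
  l <- new.env(parent = emptyenv())
  l$k <- as.integer(k); l$s <- as.integer(s); l$p <- l$k %/% 2L
  l$W <- new_param(c(k * k * cin, cout), sd = sqrt(2 / (k * k * cin)))
  l$b <- if (bias) new_param(cout, sd = 0, decay = FALSE) else NULL
  l$idx_cache <- list()
  l$params <- c(list(W = l$W), if (bias) list(b = l$b))
  class(l) <- "nn_layer"
  l
}

nn_dwconv <- function(c, k = 3, s = 1) {
  l <- new.env(parent = emptyenv())
  l$k <- as.integer(k); l$s <- as.integer(s); l$p <- l$k %/% 2L
  l$W <- new_param(c(k * k, c), sd = sqrt(2 / (k * k)))
  l$idx_cache <- list()
  l$params <- list(W = l$W)
  class(l) <- "nn_layer"
  l
}

nn_bn <- function(c, gamma_init = 1) {
  l <- new.env(parent = emptyenv())
  l$gamma <- new_param(c, init = rep(gamma_init, c), decay = FALSE)
  l$beta <- new_param(c, sd = 0, decay = FALSE)
  l$running_mean <- rep(0, c)
  l$running_var <- rep(1, c)
  l$params <- list(gamma = l$gamma, beta = l$beta)
  class(l) <- "nn_layer"
  l
}

nn_dense <- function(cin, cout, bias = TRUE) {
  l <- new.env(parent = emptyenv())
  l$W <- new_param(c(cin, cout), sd = sqrt(2 / cin))
  l$b <- if (bias) new_param(cout, sd = 0, decay = FALSE) else NULL
  l$params <- c(list(W = l$W), if (bias) list(b = l$b))
  class(l) <- "nn_layer"
  l
}

nn_maxpool <- function(k = 5, s = 1) {
  l <- new.env(parent = emptyenv())
  l$k <- as.integer(k); l$s <- as.integer(s); l$p <- l$k %/% 2L
  l$idx_cache <- list()
  l$params <- list()
  class(l) <- "nn_layer"
  l
}

op_relu <- function(tp, x) {
  m <- x$val > 0
  nd <- tape_node(tp, x$val * m, x$H, x$W, x$C, x$N,
                  bw = function(nd) nd_accum(x, nd$grad * m))
  nd
}

# generic gate broadcast: gate has one row per group; map[row_of_x] = gate row
op_mul_gate <- function(tp, x, gate, map) {
  G <- gate$val[map, , drop = FALSE]
  nd <- tape_node(tp, x$val * G, x$H, x$W, x$C, x$N, bw = function(nd) {
    nd_accum(x, nd$grad * G)
    nd_accum(gate, rowsum(nd$grad * x$val, map, reorder = TRUE))
  })
  nd
}

# mean-pool rows of x by group (groups must be 1..G, all present)
op_pool_rows <- function(tp, x, grp, counts) {
  out <- rowsum(x$val, grp, reorder = TRUE) / counts
  nd <- tape_node(tp, out, 1L, 1L, x$C, nrow(out), bw = function(nd) {
    nd_accum(x, (nd$grad / counts)[grp, , drop = FALSE])
  })
  nd
}

# ---- composite blocks ------------------------------------------------------

conv_block <- function(cin, cout, k = 1, s = 1, act = TRUE) {
  list(type = "convbn", conv = nn_conv(cin, cout, k, s), bn = nn_bn(cout),
       act = act)
}

f_conv_block <- function(tp, x, blk, training) {
  y <- op_conv(tp, x, blk$conv)
  y <- op_bn(tp, y, blk$bn, training)
  if (isTRUE(blk$act)) y <- op_silu(tp, y) else y
}

dw_block <- function(c, k = 3, s = 1, act = TRUE) {
  list(type = "dwbn", conv = nn_dwconv(c, k, s), bn = nn_bn(c), act = act)
}

f_dw_block <- function(tp, x, blk, training) {
  y <- op_conv_dw(tp, x, blk$conv)
  y <- op_bn(tp, y, blk$bn, training)
  if (isTRUE(blk$act)) y <- op_silu(tp, y) else y
}

# squeeze-excitation style channel gate (global average pool -> bottleneck
# MLP -> sigmoid); the "channel attention" unit used inside the lightweight
# bottlenecks
se_gate <- function(c, reduction = 16) {
  cr <- max(1L, c %/% reduction)
  list(type = "se", fc1 = nn_dense(c, cr), fc2 = nn_dense(cr, c))
}

f_se_gate <- function(tp, x, blk) {
  g <- op_gap(tp, x)
  g <- op_relu(tp, op_dense(tp, g, blk$fc1))
  g <- op_sigmoid(tp, op_dense(tp, g, blk$fc2))
  map <- rep(seq_len(x$N), each = x$H * x$W)
  op_mul_gate(tp, x, g, map)
}

# standard residual bottleneck of a C2f stage (two 3x3 convs)
std_bottleneck <- function(c, shortcut = TRUE) {
  list(type = "bn_std", cv1 = conv_block(c, c, 3), cv2 = conv_block(c, c, 3),
       add = shortcut)
}

f_std_bottleneck <- function(tp, x, blk, training) {
  y <- f_conv_block(tp, x, blk$cv1, training)
  y <- f_conv_block(tp, y, blk$cv2, training)
  if (isTRUE(blk$add)) op_add(tp, x, y) else y
}

# Ghost module: a small dense 1x1 "intrinsic" convolution plus a cheap
# depthwise 3x3 generating the remaining channels
ghost_module <- function(cin, cout, ratio = 2, dw_kernel = 3) {
  if (ratio < 2) stop("ghost ratio must be >= 2", call. = FALSE)
  init <- as.integer(ceiling(cout / ratio))
  cheap <- cout - init
  list(type = "ghost", init = init, cheap = cheap, cout = cout,
       primary = conv_block(cin, init, 1),
       cheap_op = dw_block(init, dw_kernel))
}

f_ghost_module <- function(tp, x, blk, training) {
  y1 <- f_conv_block(tp, x, blk$primary, training)
  y2 <- f_dw_block(tp, y1, blk$cheap_op, training)
  y <- op_concat_c(tp, list(y1, y2))
  if (y$C > blk$cout) y <- op_slice_c(tp, y, seq_len(blk$cout)) else y
}

# GC bottleneck: ghost -> channel attention -> ghost (+ residual)
gc_bottleneck <- function(c, shortcut = TRUE, reduction = 16) {
  list(type = "bn_gc", g1 = ghost_module(c, c), se = se_gate(c, reduction),
       g2 = ghost_module(c, c), add = shortcut)
}

f_gc_bottleneck <- function(tp, x, blk, training) {
  y <- f_ghost_module(tp, x, blk$g1, training)
  y <- f_se_gate(tp, y, blk$se)
  y <- f_ghost_module(tp, y, blk$g2, training)
  if (isTRUE(blk$add)) op_add(tp, x, y) else y
}

# GSConv: half-dense / half-depthwise convolution with channel shuffle
gs_conv <- function(cin, cout, k = 1, s = 1) {
  if (cout %% 2L != 0L) stop("gs_conv needs an even output width", call. = FALSE)
  c_ <- cout %/% 2L
  perm <- as.vector(rbind(seq_len(c_), c_ + seq_len(c_)))
  list(type = "gsconv", c_ = c_, perm = perm,
       dense = conv_block(cin, c_, k, s), dw = dw_block(c_, 3))
}

f_gs_conv <- function(tp, x, blk, training) {
  y1 <- f_conv_block(tp, x, blk$dense, training)
  y2 <- f_dw_block(tp, y1, blk$dw, training)
  y <- op_concat_c(tp, list(y1, y2))
  op_permute_c(tp, y, blk$perm)
}

# SC bottleneck: GSConv (1x1) -> channel attention -> GSConv (3x3)
sc_bottleneck <- function(c, shortcut = TRUE, reduction = 16) {
  list(type = "bn_sc", gs1 = gs_conv(c, c, 1), se = se_gate(c, reduction),
       gs2 = gs_conv(c, c, 3), add = shortcut)
}

f_sc_bottleneck <- function(tp, x, blk, training) {
  y <- f_gs_conv(tp, x, blk$gs1, training)
  y <- f_se_gate(tp, y, blk$se)
  y <- f_gs_conv(tp, y, blk$gs2, training)
  if (isTRUE(blk$add)) op_add(tp, x, y) else y
}

f_bottleneck <- function(tp, x, blk, training) {
  switch(blk$type,
         bn_std = f_std_bottleneck(tp, x, blk, training),
         bn_gc = f_gc_bottleneck(tp, x, blk, training),
         bn_sc = f_sc_bottleneck(tp, x, blk, training),
         stop("unknown bottleneck type ", blk$type))
}

# C2f: split-transform-concatenate stage with n internal bottlenecks
c2f_block <- function(cin, cout, n, shortcut = FALSE,
                      kind = c("std", "gc", "sc"), reduction = 16) {
  kind <- match.arg(kind)
  c <- cout %/% 2L
  mk <- switch(kind,
               std = function() std_bottleneck(c, shortcut),
               gc = function() gc_bottleneck(c, shortcut, reduction),
               sc = function() sc_bottleneck(c, shortcut, reduction))
  list(type = "c2f", c = c, n = n,
       cv1 = conv_block(cin, 2L * c, 1),
       cv2 = conv_block((2L + n) * c, cout, 1),
       ms = lapply(seq_len(n), function(i) mk()))
}

f_c2f <- function(tp, x, blk, training) {
  y <- f_conv_block(tp, x, blk$cv1, training)
  a <- op_slice_c(tp, y, seq_len(blk$c))
  b <- op_slice_c(tp, y, blk$c + seq_len(blk$c))
  parts <- list(a, b)
  cur <- b
  for (m in blk$ms) {
    cur <- f_bottleneck(tp, cur, m, training)
    parts[[length(parts) + 1L]] <- cur
  }
  f_conv_block(tp, op_concat_c(tp, parts), blk$cv2, training)
}

sppf_block <- function(c) {
  c_ <- c %/% 2L
  list(type = "sppf", cv1 = conv_block(c, c_, 1), mp = nn_maxpool(5, 1),
       cv2 = conv_block(4L * c_, c, 1))
}

f_sppf <- function(tp, x, blk, training) {
  y <- f_conv_block(tp, x, blk$cv1, training)
  p1 <- op_maxpool(tp, y, blk$mp)
  p2 <- op_maxpool(tp, p1, blk$mp)
  p3 <- op_maxpool(tp, p2, blk$mp)
  f_conv_block(tp, op_concat_c(tp, list(y, p1, p2, p3)), blk$cv2, training)
}

# ---- attention blocks for the FPN -----------------------------------------

cbam_block <- function(c, reduction = 16) {
  cr <- max(1L, c %/% reduction)
  list(type = "cbam", fc1 = nn_dense(c, cr), fc2 = nn_dense(cr, c),
       spat = nn_conv(2, 1, 7, bias = TRUE))
}

f_cbam <- function(tp, x, blk, training) {
  avg <- op_gap(tp, x); mx <- op_gmp(tp, x)
  h1 <- op_dense(tp, op_relu(tp, op_dense(tp, avg, blk$fc1)), blk$fc2)
  h2 <- op_dense(tp, op_relu(tp, op_dense(tp, mx, blk$fc1)), blk$fc2)
  gate_c <- op_sigmoid(tp, op_add(tp, h1, h2))
  map <- rep(seq_len(x$N), each = x$H * x$W)
  y <- op_mul_gate(tp, x, gate_c, map)
  mm <- op_chan_meanmax(tp, y)
  gate_s <- op_sigmoid(tp, op_conv(tp, mm, blk$spat))
  op_mul_spatial_gate(tp, y, gate_s)
}

# coordinate attention: directional (per-row / per-column) pooled descriptors
# gate the map along each axis; the shared bottleneck conv is applied to each
# pooled descriptor separately
ca_block <- function(c, reduction = 16) {
  cr <- max(1L, c %/% reduction)
  list(type = "ca", mid = nn_dense(c, cr), bnm = nn_bn(cr),
       to_h = nn_dense(cr, c), to_w = nn_dense(cr, c))
}

f_ca <- function(tp, x, blk, training) {
  S <- x$H * x$W
  xs <- rep(seq_len(x$W), times = x$H * x$N)
  ys <- rep(rep(seq_len(x$H), each = x$W), times = x$N)
  nn <- rep(seq_len(x$N), each = S)
  grp_h <- ys + (nn - 1L) * x$H   # pool along W: one row per (n, y)
  grp_w <- xs + (nn - 1L) * x$W   # pool along H: one row per (n, x)
  ph <- op_pool_rows(tp, x, grp_h, x$W)
  pw <- op_pool_rows(tp, x, grp_w, x$H)
  mid <- function(p) op_silu(tp, op_bn(tp, op_dense(tp, p, blk$mid), blk$bnm,
                                       training))
  gh <- op_sigmoid(tp, op_dense(tp, mid(ph), blk$to_h))
  gw <- op_sigmoid(tp, op_dense(tp, mid(pw), blk$to_w))
  y <- op_mul_gate(tp, x, gh, grp_h)
  op_mul_gate(tp, y, gw, grp_w)
}

se_block <- function(c, reduction = 16) {
  se <- se_gate(c, reduction)
  se$type <- "se_block"
  se
}

nonlocal_block <- function(c) {
  c_ <- max(1L, c %/% 2L)
  list(type = "nonlocal", c_ = c_,
       theta = nn_conv(c, c_, 1, bias = TRUE),
       phi = nn_conv(c, c_, 1, bias = TRUE),
       g = nn_conv(c, c_, 1, bias = TRUE),
       out = nn_conv(c_, c, 1, bias = TRUE),
       bn_out = nn_bn(c, gamma_init = 0))  # residual branch starts at zero
}

f_nonlocal <- function(tp, x, blk, training) {
  th <- op_conv(tp, x, blk$theta)
  ph <- op_conv(tp, x, blk$phi)
  gg <- op_conv(tp, x, blk$g)
  sc <- op_matmul_persample(tp, th, ph, transpose_b = TRUE)
  A <- op_row_softmax(tp, sc)
  y <- op_matmul_persample(tp, A, gg)
  y <- op_bn(tp, op_conv(tp, y, blk$out), blk$bn_out, training)
  op_add(tp, x, y)
}

#' Build a feature-pyramid attention block
#'
#' Constructs one of the four attention units that can be inserted after
#' each neck fusion: `ca` (coordinate attention), `se`
#' (squeeze-excitation channel gate), `cbam` (channel gate followed by a
#' 7 x 7 spatial gate), or `nonlocal` (embedded-Gaussian pairwise attention
#' with a zero-initialized residual projection). All are shape-preserving.
#'
#' @param kind one of `"ca"`, `"se"`, `"cbam"`, `"nonlocal"`.
#' @param channels number of feature channels (must be at least `reduction`).
#' @param reduction bottleneck reduction ratio of the gating MLPs.
#' @return An attention block usable inside a detector; exposed mainly for
#'   inspection and unit testing.
#' @export
attention_block <- function(kind, channels, reduction = 16) {
  kind <- match.arg(kind, c("ca", "se", "cbam", "nonlocal"))
  if (kind != "nonlocal" && channels < reduction) {
    stop("channels (", channels, ") must be >= reduction (", reduction, ")",
         call. = FALSE)
  }
  switch(kind,
         ca = ca_block(channels, reduction),
         se = se_block(channels, reduction),
         cbam = cbam_block(channels, reduction),
         nonlocal = nonlocal_block(channels))
}

f_attention <- function(tp, x, blk, training) {
  switch(blk$type,
         ca = f_ca(tp, x, blk, training),
         se_block = f_se_gate(tp, x, blk),
         cbam = f_cbam(tp, x, blk, training),
         nonlocal = f_nonlocal(tp, x, blk, training))
}

# ---- parameter collection --------------------------------------------------

collect_params <- function(x) {
  if (inherits(x, "nn_param")) return(list(x))
  if (inherits(x, "nn_layer")) return(unname(x$params))
  if (is.list(x)) {
    sub <- lapply(x, function(e) {
      if (inherits(e, c("nn_param", "nn_layer")) || is.list(e)) {
        collect_params(e)
      } else list()
    })
    return(unlist(sub, recursive = FALSE, use.names = FALSE))
  }
  list()
}
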