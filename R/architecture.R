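#' Detector architecture configuration
#'
#' Describes one member of the lightweight detector family: the compact
#' `baseline` (n-scale one-stage anchor-free detector: stem + four C2f
#' stages with SPPF, top-down/bottom-up feature-pyramid neck, decoupled
#' distribution-regression head at strides 8/16/32), and three lightweight
#' variants obtained by rebuilding the C2f bottlenecks:
#'
#' * `gnca` — every C2f bottleneck becomes a GC bottleneck
#'   (ghost module, channel attention, ghost module);
#' * `snca` — every C2f bottleneck becomes an SC bottleneck
#'   (GSConv, channel attention, GSConv);
#' * `gsca` — GC bottlenecks in the backbone, SC bottlenecks in the neck.
#'
#' The named variants carry CBAM attention after each neck fusion by
#' default; `fpn_attention` overrides this.
#'
#' @param variant `"baseline"`, `"gnca"`, `"snca"` or `"gsca"`.
#' @param nc number of object classes (4 behavior classes by default).
#' @param depth_multiple,width_multiple,max_channels n-scale compound
#'   scaling factors (0.33 / 0.25 / 1024).
#' @param reg_max number of distribution-regression bins per box side.
#' @param fpn_attention `"none"`, `"ca"`, `"se"`, `"cbam"` or `"nonlocal"`;
#'   `NULL` selects the variant default (none for baseline, cbam otherwise).
#' @param ghost_ratio ghost module compression ratio (`>= 2`).
#' @param attention_reduction reduction ratio of the gating MLPs.
#' @return A `detector_config` list.
#' @export
detector_config <- function(variant = c("baseline", "gnca", "snca", "gsca"),
                            nc = 4, depth_multiple = 0.33,
                            width_multiple = 0.25, max_channels = 1024,
                            reg_max = 16, fpn_attention = NULL,
                            ghost_ratio = 2, attention_reduction = 16) {
  variant <- match.arg(variant)
  if (is.null(fpn_attention)) {
    fpn_attention <- if (variant == "baseline") "none" else "cbam"
  }
  fpn_attention <- match.arg(fpn_attention,
                             c("none", "ca", "se", "cbam", "nonlocal"))
  stopifnot(nc >= 1, reg_max >= 2, depth_multiple > 0, width_multiple > 0,
            ghost_ratio >= 2)
  structure(list(variant = variant, nc = as.integer(nc),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 max_channels = as.integer(max_channels),
                 reg_max = as.integer(reg_max),
                 fpn_attention = fpn_attention,
                 ghost_ratio = as.integer(ghost_ratio),
                 attention_reduction = as.integer(attention_reduction)),
            class = "detector_config")
}

# scaled channel width / repeat count
.cw <- function(c, config) {
  max(8L, as.integer(round(min(c, config$max_channels) *
                             config$width_multiple / 8) * 8))
}
.cn <- function(n, config) max(1L, as.integer(ceiling(n * config$depth_multiple)))

#' Build a behavior detector
#'
#' Assembles the network described by a [detector_config()]: stem and four
#' backbone stages (C2f repeats 3/6/6/3 before depth scaling) with SPPF,
#' a top-down plus bottom-up feature-pyramid neck with four C2f fusion
#' blocks (and an optional attention block after each fusion), and a
#' decoupled anchor-free head predicting a 4 x `reg_max` box distribution
#' and `nc` class logits at strides 8, 16 and 32.
#'
#' @param config a [detector_config()] (or a variant name).
#' @param seed integer seed for weight initialization.
#' @return An object of class `goat_detector`.
#' @export
#' @examples
#' det <- build_detector(detector_config("baseline"), seed = 1)
#' count_parameters(det)
build_detector <- function(config = detector_config(), seed = 0) {
  if (is.character(config)) config <- detector_config(config)
  stopifnot(inherits(config, "detector_config"))
  with_seed(seed, .assemble_detector(config))
}

.assemble_detector <- function(config) {
  red <- config$attention_reduction
  bk <- switch(config$variant, baseline = "std", gnca = "gc", snca = "sc",
               gsca = "gc")
  nk <- switch(config$variant, baseline = "std", gnca = "gc", snca = "sc",
               gsca = "sc")
  w <- vapply(c(64, 128, 256, 512, 1024), .cw, 0L, config = config)
  # n-scale: 16, 32, 64, 128, 256
  n1 <- .cn(3, config); n2 <- .cn(6, config)
  m <- list()
  m$stem <- conv_block(3, w[1], 3, 2)
  m$down2 <- conv_block(w[1], w[2], 3, 2)
  m$stage2 <- c2f_block(w[2], w[2], n1, TRUE, bk, red)
  m$down3 <- conv_block(w[2], w[3], 3, 2)
  m$stage3 <- c2f_block(w[3], w[3], n2, TRUE, bk, red)
  m$down4 <- conv_block(w[3], w[4], 3, 2)
  m$stage4 <- c2f_block(w[4], w[4], n2, TRUE, bk, red)
  m$down5 <- conv_block(w[4], w[5], 3, 2)
  m$stage5 <- c2f_block(w[5], w[5], n1, TRUE, bk, red)
  m$sppf <- sppf_block(w[5])
  # neck: top-down then bottom-up
  m$neck_td4 <- c2f_block(w[5] + w[4], w[4], n1, FALSE, nk, red)
  m$neck_td3 <- c2f_block(w[4] + w[3], w[3], n1, FALSE, nk, red)
  m$neck_down3 <- conv_block(w[3], w[3], 3, 2)
  m$neck_bu4 <- c2f_block(w[3] + w[4], w[4], n1, FALSE, nk, red)
  m$neck_down4 <- conv_block(w[4], w[4], 3, 2)
  m$neck_bu5 <- c2f_block(w[4] + w[5], w[5], n1, FALSE, nk, red)
  if (config$fpn_attention != "none") {
    m$attn <- lapply(c(w[4], w[3], w[4], w[5]), function(ch)
      attention_block(config$fpn_attention, ch, red))
  }
  ch <- c(w[3], w[4], w[5])
  c2 <- max(16L, ch[1] %/% 4L, 4L * config$reg_max)
  c3 <- max(ch[1], min(config$nc, 100L))
  m$head <- lapply(ch, function(ci) {
    list(box1 = conv_block(ci, c2, 3), box2 = conv_block(c2, c2, 3),
         box_out = nn_conv(c2, 4L * config$reg_max, 1, bias = TRUE),
         cls1 = conv_block(ci, c3, 3), cls2 = conv_block(c3, c3, 3),
         cls_out = nn_conv(c3, config$nc, 1, bias = TRUE))
  })
  # prior-style init: rare-positive classification at start
  for (hd in m$head) {
    hd$cls_out$b$val[] <- -log((1 - 0.01) / 0.01)
    hd$box_out$b$val[] <- 0
  }
  det <- structure(list(config = config, modules = m,
                        strides = c(8L, 16L, 32L), channels = w,
                        head_widths = c(box = c2, cls = c3)),
                   class = "goat_detector")
  det$params <- collect_params(m)
  det
}

#' Count trainable parameters
#'
#' Exact number of trainable scalar weights of a detector (convolution and
#' dense weights, biases, and batch-norm scale/shift; running statistics are
#' buffers, not parameters).
#'
#' @param detector a `goat_detector` (or any block/layer built by this
#'   package).
#' @return Integer parameter count.
#' @export
count_parameters <- function(detector) {
  ps <- if (inherits(detector, "goat_detector")) detector$params else
    collect_params(detector)
  sum(vapply(ps, param_size, 0))
}

#' @export
print.goat_detector <- function(x, ...) {
  cat(sprintf("<goat_detector> variant '%s', %d classes, attention '%s'\n",
              x$config$variant, x$config$nc, x$config$fpn_attention))
  cat(sprintf("  %s trainable parameters (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' @export
summary.goat_detector <- function(object, ...) {
  m <- object$modules
  groups <- list(
    backbone = m[c("stem", "down2", "stage2", "down3", "stage3", "down4",
                   "stage4", "down5", "stage5", "sppf")],
    neck = m[c("neck_td4", "neck_td3", "neck_down3", "neck_bu4",
               "neck_down4", "neck_bu5")],
    attention = if (!is.null(m$attn)) m$attn else list(),
    head = m$head)
  tab <- data.frame(
    module = names(groups),
    parameters = vapply(groups, function(g)
      sum(vapply(collect_params(g), param_size, 0)), 0))
  tab$share <- tab$parameters / sum(tab$parameters)
  out <- list(config = object$config, breakdown = tab,
              total = count_parameters(object))
  class(out) <- "summary.goat_detector"
  out
}

#' @export
print.summary.goat_detector <- function(x, ...) {
  cat(sprintf("Detector variant '%s' (nc = %d, fpn attention '%s')\n",
              x$config$variant, x$config$nc, x$config$fpn_attention))
  print(transform(x$breakdown, share = sprintf("%.1f%%", 100 * share)),
        row.names = FALSE)
  cat(sprintf("total: %s parameters (%.2f M)\n",
              format(x$total, big.mark = ","), x$total / 1e6))
  invisible(x)
}

# Forward pass to the three raw head outputs. `imgs` is a list of equally
# sized H x W x 3 rasters with H, W divisible by 32.
forward_detector <- function(detector, imgs, training = FALSE, tape = NULL) {
  m <- detector$modules
  if (is.null(tape)) tape <- new_tape()
  d <- dim(imgs[[1]])
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("input size must be divisible by 32", call. = FALSE)
  }
  x <- images_to_node(tape, imgs)
  x <- f_conv_block(tape, x, m$stem, training)
  x <- f_conv_block(tape, x, m$down2, training)
  x <- f_c2f(tape, x, m$stage2, training)
  x <- f_conv_block(tape, x, m$down3, training)
  p3 <- f_c2f(tape, x, m$stage3, training)
  x <- f_conv_block(tape, p3, m$down4, training)
  p4 <- f_c2f(tape, x, m$stage4, training)
  x <- f_conv_block(tape, p4, m$down5, training)
  x <- f_c2f(tape, x, m$stage5, training)
  p5 <- f_sppf(tape, x, m$sppf, training)
  att <- function(i, nd) {
    if (is.null(m$attn)) nd else f_attention(tape, nd, m$attn[[i]], training)
  }
  u4 <- op_concat_c(tape, list(op_upsample2(tape, p5), p4))
  t4 <- att(1, f_c2f(tape, u4, m$neck_td4, training))
  u3 <- op_concat_c(tape, list(op_upsample2(tape, t4), p3))
  t3 <- att(2, f_c2f(tape, u3, m$neck_td3, training))
  d4 <- op_concat_c(tape, list(f_conv_block(tape, t3, m$neck_down3, training), t4))
  b4 <- att(3, f_c2f(tape, d4, m$neck_bu4, training))
  d5 <- op_concat_c(tape, list(f_conv_block(tape, b4, m$neck_down4, training), p5))
  b5 <- att(4, f_c2f(tape, d5, m$neck_bu5, training))
  feats <- list(t3, b4, b5)
  outs <- lapply(1:3, function(i) {
    hd <- m$head[[i]]
    f <- feats[[i]]
    bx <- f_conv_block(tape, f, hd$box1, training)
    bx <- f_conv_block(tape, bx, hd$box2, training)
    bx <- op_conv(tape, bx, hd$box_out)
    cl <- f_conv_block(tape, f, hd$cls1, training)
    cl <- f_conv_block(tape, cl, hd$cls2, training)
    cl <- op_conv(tape, cl, hd$cls_out)
    list(box = bx, cls = cl, H = f$H, W = f$W,
         stride = detector$strides[i])
  })
  list(tape = tape, outputs = outs, neck = feats, n = length(imgs))
}

#' Save or load detector weights
#'
#' Weights (including batch-norm running statistics) are serialized with
#' R's native RDS container in parameter-collection order.
#'
#' @param detector a `goat_detector`.
#' @param path file path.
#' @return `load_detector_weights()` returns the detector, invisibly.
#' @export
save_detector_weights <- function(detector, path) {
  vals <- lapply(detector$params, function(p) p$val)
  bufs <- .bn_buffers(detector$modules)
  saveRDS(list(config = detector$config, values = vals,
               buffers = lapply(bufs, function(b)
                 list(mean = b$running_mean, var = b$running_var))), path)
  invisible(path)
}

#' @rdname save_detector_weights
#' @export
load_detector_weights <- function(detector, path) {
  st <- readRDS(path)
  stopifnot(length(st$values) == length(detector$params))
  for (i in seq_along(st$values)) detector$params[[i]]$val <- st$values[[i]]
  bufs <- .bn_buffers(detector$modules)
  stopifnot(length(bufs) == length(st$buffers))
  for (i in seq_along(bufs)) {
    bufs[[i]]$running_mean <- st$buffers[[i]]$mean
    bufs[[i]]$running_var <- st$buffers[[i]]$var
  }
  invisible(detector)
}

.bn_buffers <- function(x) {
  if (inherits(x, "nn_layer")) {
    return(if (!is.null(x$running_mean)) list(x) else list())
  }
  if (is.list(x)) {
    return(unlist(lapply(x, function(e) {
      if (inherits(e, "nn_layer") || is.list(e)) .bn_buffers(e) else list()
    }), recursive = FALSE, use.names = FALSE))
  }
  list()
}
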