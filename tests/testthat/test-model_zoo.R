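# numeric gradient check helper for a scalar-valued forward closure
num_grad <- function(fwd, param, i, eps = 1e-5) {
  param$val[i] <- param$val[i] + eps; up <- fwd()
  param$val[i] <- param$val[i] - 2 * eps; dn <- fwd()
  param$val[i] <- param$val[i] + eps
  (up - dn) / (2 * eps)
}

test_that("autodiff gradients match numeric differentiation", {
  set.seed(1)
  imgs <- list(array(runif(12 * 12 * 3, 0, 255), c(12, 12, 3)),
               array(runif(12 * 12 * 3, 0, 255), c(12, 12, 3)))
  blocks <- list(
    dense_conv = caprimon:::conv_block(3, 6, 3, 2),
    c2f = caprimon:::c2f_block(3, 8, 2, TRUE, "std"),
    ghost = caprimon:::gc_bottleneck(4, TRUE, 2),
    gs = caprimon:::sc_bottleneck(4, TRUE, 2),
    sppf = caprimon:::sppf_block(4),
    cbam = caprimon:::cbam_block(8, 4),
    ca = caprimon:::ca_block(8, 4),
    nl = caprimon:::nonlocal_block(6))
  fwd_for <- list(
    dense_conv = function(tp, x, b) caprimon:::f_conv_block(tp, x, b, TRUE),
    c2f = function(tp, x, b) caprimon:::f_c2f(tp, x, b, TRUE),
    ghost = function(tp, x, b) {
      x4 <- caprimon:::op_slice_c(tp, x, c(1, 2, 3, 1))
      caprimon:::f_gc_bottleneck(tp, x4, b, TRUE)
    },
    gs = function(tp, x, b) {
      x4 <- caprimon:::op_slice_c(tp, x, c(1, 2, 3, 1))
      caprimon:::f_sc_bottleneck(tp, x4, b, TRUE)
    },
    sppf = function(tp, x, b) {
      x4 <- caprimon:::op_slice_c(tp, x, c(1, 2, 3, 1))
      caprimon:::f_sppf(tp, x4, b, TRUE)
    },
    cbam = function(tp, x, b) {
      x8 <- caprimon:::op_concat_c(tp, list(x, x))
      x8 <- caprimon:::op_slice_c(tp, x8, c(1:6, 1, 2))
      caprimon:::f_cbam(tp, x8, b, TRUE)
    },
    ca = function(tp, x, b) {
      x8 <- caprimon:::op_concat_c(tp, list(x, x))
      x8 <- caprimon:::op_slice_c(tp, x8, c(1:6, 1, 2))
      caprimon:::f_ca(tp, x8, b, TRUE)
    },
    nl = function(tp, x, b) {
      x6 <- caprimon:::op_concat_c(tp, list(x, x))
      caprimon:::f_nonlocal(tp, x6, b, TRUE)
    })
  for (nm in names(blocks)) {
    blk <- blocks[[nm]]
    run <- function() {
      tp <- caprimon:::new_tape()
      x <- caprimon:::images_to_node(tp, imgs)
      y <- fwd_for[[nm]](tp, x, blk)
      # fixed pseudo-random projection makes the scalar sensitive everywhere
      set.seed(99)
      w <- matrix(rnorm(length(y$val)), nrow(y$val))
      s <- caprimon:::ew_mean(tp, caprimon:::ew_mul(
        tp, y, caprimon:::tape_node(tp, w, y$H, y$W, y$C, y$N)))
      list(tp = tp, s = s)
    }
    out <- run()
    caprimon:::tape_backward(out$tp, out$s)
    ps <- caprimon:::collect_params(blk)
    for (pi in seq(1, length(ps), by = max(1, length(ps) %/% 4))) {
      p <- ps[[pi]]
      i <- ((pi * 7) %% length(p$val)) + 1
      g_num <- num_grad(function() run()$s$val[1], p, i)
      expect_equal(p$grad[i], g_num, tolerance = 1e-4,
                   info = paste(nm, "param", pi))
      p$grad[] <- 0
    }
    for (p in ps) p$grad[] <- 0
  }
})

test_that("ghost modules have the declared channel split and fewer parameters", {
  g <- caprimon:::ghost_module(64, 128, ratio = 2)
  expect_equal(g$init, 64)
  expect_equal(g$cheap, 64)
  # spatial size preserved, output exactly 128 channels
  tp <- caprimon:::new_tape()
  set.seed(2)
  x <- caprimon:::tape_node(tp, matrix(rnorm(36 * 64), 36, 64), 6L, 6L, 64L, 1L)
  y <- caprimon:::f_ghost_module(tp, x, g, TRUE)
  expect_equal(c(y$H, y$W, y$C), c(6, 6, 128))
  # parameter count strictly below a dense 3x3 convolution 64 -> 128
  n_ghost <- sum(vapply(caprimon:::collect_params(g), caprimon:::param_size, 0))
  n_dense <- 3 * 3 * 64 * 128 + 2 * 128
  expect_lt(n_ghost, n_dense)
  expect_error(caprimon:::ghost_module(8, 8, ratio = 1), "ratio")
})

test_that("GSConv interleaves its halves and is cheaper than dense", {
  gs <- caprimon:::gs_conv(64, 64, 3)
  # the shuffle is the perfect interleave permutation
  expect_equal(gs$perm[1:6], c(1, 33, 2, 34, 3, 35))
  expect_setequal(gs$perm, 1:64)
  n_gs <- sum(vapply(caprimon:::collect_params(gs), caprimon:::param_size, 0))
  expect_lt(n_gs, 3 * 3 * 64 * 64 + 2 * 64)
  expect_error(caprimon:::gs_conv(8, 7), "even")
  # channel-identity trace: tag input channels, check output ordering
  tp <- caprimon:::new_tape()
  gs2 <- caprimon:::gs_conv(4, 8, 1)
  x <- caprimon:::tape_node(tp, matrix(1, 4, 4), 2L, 2L, 4L, 1L)
  y1 <- caprimon:::f_conv_block(tp, x, gs2$dense, TRUE)
  y2 <- caprimon:::f_dw_block(tp, y1, gs2$dw, TRUE)
  yc <- caprimon:::op_concat_c(tp, list(y1, y2))
  ys <- caprimon:::op_permute_c(tp, yc, gs2$perm)
  # sorted multiset of output channels equals the pre-shuffle multiset
  expect_equal(sort(as.vector(ys$val)), sort(as.vector(yc$val)))
  expect_equal(ys$val[, 1], yc$val[, 1])  # first dense channel stays first
  expect_equal(ys$val[, 2], yc$val[, 5])  # then the first depthwise channel
})

test_that("lightweight C2f variants undercut the standard block", {
  count <- function(b) sum(vapply(caprimon:::collect_params(b),
                                  caprimon:::param_size, 0))
  std <- caprimon:::c2f_block(64, 64, 2, TRUE, "std")
  gc <- caprimon:::c2f_block(64, 64, 2, TRUE, "gc")
  sc <- caprimon:::c2f_block(64, 64, 2, TRUE, "sc")
  expect_lt(count(gc), count(std))
  expect_lt(count(sc), count(std))
  expect_lt(count(gc), count(sc))
  # shortcut = FALSE removes the additive path
  nsc <- caprimon:::c2f_block(8, 8, 1, FALSE, "std")
  expect_false(isTRUE(nsc$ms[[1]]$add))
})

test_that("attention blocks are shape preserving with gates in (0, 1)", {
  set.seed(3)
  tp <- caprimon:::new_tape()
  x <- caprimon:::tape_node(tp, matrix(rnorm(2 * 16 * 16), 32, 16),
                            4L, 4L, 16L, 2L)
  for (kind in c("ca", "se", "cbam", "nonlocal")) {
    blk <- attention_block(kind, 16, reduction = 8)
    y <- caprimon:::f_attention(tp, x, blk, TRUE)
    expect_equal(c(y$H, y$W, y$C, nrow(y$val)), c(4, 4, 16, 32),
                 info = kind)
  }
  expect_error(attention_block("se", 4, reduction = 16), "reduction")
  # SE gate values lie strictly in (0, 1)
  se <- caprimon:::se_gate(16, 8)
  g <- caprimon:::op_sigmoid(tp, caprimon:::op_dense(
    tp, caprimon:::op_relu(tp, caprimon:::op_dense(
      tp, caprimon:::op_gap(tp, x), se$fc1)), se$fc2))
  expect_true(all(g$val > 0 & g$val < 1))
  # spatially uniform input -> uniform CBAM spatial gate away from the
  # zero-padded border (the 7x7 gate convolution sees padding at the edge)
  xu <- caprimon:::tape_node(tp, matrix(rep(rnorm(16), each = 256), 256, 16),
                             16L, 16L, 16L, 1L)
  cb <- caprimon:::cbam_block(16, 8)
  mm <- caprimon:::op_chan_meanmax(tp, xu)
  gs <- caprimon:::op_sigmoid(tp, caprimon:::op_conv(tp, mm, cb$spat))
  gmat <- matrix(gs$val[, 1], 16, 16, byrow = TRUE)
  expect_lt(diff(range(gmat[4:13, 4:13])), 1e-9)
  # non-local block with its zero-initialized output projection is identity
  nl <- caprimon:::nonlocal_block(16)
  yz <- caprimon:::f_nonlocal(tp, x, nl, FALSE)
  expect_equal(yz$val, x$val, tolerance = 1e-12)
})

test_that("letterboxing is exact and invertible", {
  img <- flat_image(640, 640, 50)
  lb <- letterbox(img, 640)
  expect_equal(lb$scale, 1)
  expect_equal(lb$pad_x + lb$pad_y, 0)
  expect_equal(lb$canvas, img)
  wide <- flat_image(720, 1280, 90)
  lb2 <- letterbox(wide, 640)
  expect_equal(lb2$pad_y, 140)
  expect_equal(lb2$pad_x, 0)
  # gray bands at value 114 top and bottom
  expect_true(all(lb2$canvas[1:140, , ] == 114))
  expect_true(all(lb2$canvas[501:640, , ] == 114))
  expect_true(all(lb2$canvas[141:500, , ] == 90))
  b <- random_box_table(50, 1280, 720, seed = 6)
  rt <- boxes_to_source(boxes_to_canvas(b, lb2), lb2)
  expect_lt(max(abs(as.matrix(rt[, 1:4]) - as.matrix(b[, 1:4]))), 1)
})

test_that("NMS equals the brute-force suppression oracle", {
  two <- boxes(c(10, 10), c(10, 10), c(30, 30), c(40, 40), c("eat", "eat"),
               conf = c(0.9, 0.9))
  expect_equal(nrow(nms_boxes(two, 0.5)), 1)
  # brute force: walk detections by descending score within each class and
  # drop any box overlapping a kept one
  brute <- function(det, thr) {
    keep <- logical(nrow(det))
    for (cl in unique(det$cls)) {
      idx <- which(det$cls == cl)
      idx <- idx[order(-det$conf[idx], idx)]
      for (i in idx) {
        ok <- TRUE
        for (j in which(keep & det$cls == cl)) {
          if (box_iou_matrix(det[i, ], det[j, ])[1, 1] > thr) ok <- FALSE
        }
        keep[i] <- ok
      }
    }
    which(keep)
  }
  for (s in 1:20) {
    det <- random_box_table(50, 60, 60, seed = 100 + s, conf = TRUE)
    got <- nms_boxes(det, 0.5)
    want <- det[brute(det, 0.5), , drop = FALSE]
    rownames(want) <- NULL
    expect_equal(got[order(got$x1, got$y1), ],
                 want[order(want$x1, want$y1), ], ignore_attr = TRUE)
  }
})

test_that("detectors build with stride-consistent maps for any /32 size", {
  det <- build_detector(detector_config("baseline"), seed = 1)
  for (sz in c(64, 96)) {
    img <- noisy_image(sz, sz, seed = sz)
    fw <- caprimon:::forward_detector(det, list(img))
    expect_equal(vapply(fw$outputs, function(o) o$H, 0L), sz %/% c(8, 16, 32))
    expect_equal(vapply(fw$outputs, function(o) o$box$C, 0L), rep(64L, 3))
    expect_equal(vapply(fw$outputs, function(o) o$cls$C, 0L), rep(4L, 3))
  }
  expect_error(caprimon:::forward_detector(det, list(noisy_image(50, 50))),
               "divisible by 32")
  expect_error(detector_config("resnet"), "arg")
})

test_that("random detectors emit valid (possibly empty) detections", {
  det <- build_detector(detector_config("snca"), seed = 4)
  img <- small_scene(seed = 2, n_goats = 2, size = c(160, 160))
  out <- predict(det, img, input_size = 64)
  expect_true(is.data.frame(out))
  if (nrow(out)) {
    expect_true(all(out$conf >= 0.001))
    expect_true(all(out$cls %in% behavior_classes()))
    expect_true(all(out$x1 < out$x2 & out$y1 < out$y2))
    expect_true(all(out$x1 >= 0 & out$y1 >= 0 & out$x2 <= 160 & out$y2 <= 160))
  }
})

test_that("parameter counting is exact on small known modules", {
  # one affine map 4 -> 2 with bias: 10 parameters
  expect_equal(count_parameters(caprimon:::nn_dense(4, 2)), 10)
  expect_equal(count_parameters(caprimon:::nn_conv(3, 8, 3)), 3 * 3 * 3 * 8)
  expect_equal(count_parameters(caprimon:::conv_block(3, 8, 3)),
               3 * 3 * 3 * 8 + 16)
})

test_that("variant parameter counts match the analytic layer-by-layer oracle", {
  # independent bookkeeping from the written layer plan
  conv_n <- function(cin, cout, k, bias = FALSE, bn = TRUE)
    k * k * cin * cout + bias * cout + bn * 2 * cout
  se_n <- function(c, r = 16) { cr <- max(1, c %/% r); c * cr + cr + cr * c + c }
  ghost_n <- function(cin, cout) {
    init <- ceiling(cout / 2)
    conv_n(cin, init, 1) + 9 * init + 2 * init
  }
  gs_n <- function(cin, cout, k) {
    c_ <- cout / 2
    conv_n(cin, c_, k) + 9 * c_ + 2 * c_
  }
  bneck_n <- function(c, kind) {
    switch(kind,
           std = 2 * conv_n(c, c, 3),
           gc = 2 * ghost_n(c, c) + se_n(c),
           sc = gs_n(c, c, 1) + se_n(c) + gs_n(c, c, 3))
  }
  c2f_n <- function(cin, cout, n, kind) {
    c <- cout / 2
    conv_n(cin, 2 * c, 1) + conv_n((2 + n) * c, cout, 1) +
      n * bneck_n(c, kind)
  }
  cbam_n <- function(c) se_n(c) + (7 * 7 * 2 + 1)
  head_n <- function(nc) {
    c2 <- 64; c3 <- 64
    sum(vapply(c(64, 128, 256), function(ch)
      conv_n(ch, c2, 3) + conv_n(c2, c2, 3) + (c2 * 64 + 64) +
        conv_n(ch, c3, 3) + conv_n(c3, c3, 3) + (c3 * nc + nc), 0))
  }
  model_n <- function(bk, nk, attn) {
    conv_n(3, 16, 3) + conv_n(16, 32, 3) + c2f_n(32, 32, 1, bk) +
      conv_n(32, 64, 3) + c2f_n(64, 64, 2, bk) +
      conv_n(64, 128, 3) + c2f_n(128, 128, 2, bk) +
      conv_n(128, 256, 3) + c2f_n(256, 256, 1, bk) +
      conv_n(256, 128, 1) + conv_n(4 * 128, 256, 1) +  # sppf
      c2f_n(384, 128, 1, nk) + c2f_n(192, 64, 1, nk) +
      conv_n(64, 64, 3) + c2f_n(192, 128, 1, nk) +
      conv_n(128, 128, 3) + c2f_n(384, 256, 1, nk) +
      (if (attn) cbam_n(128) + cbam_n(64) + cbam_n(128) + cbam_n(256) else 0) +
      head_n(4)
  }
  expect_equal(count_parameters(build_detector("baseline")),
               model_n("std", "std", FALSE))
  expect_equal(count_parameters(build_detector("gnca")),
               model_n("gc", "gc", TRUE))
  expect_equal(count_parameters(build_detector("snca")),
               model_n("sc", "sc", TRUE))
  expect_equal(count_parameters(build_detector("gsca")),
               model_n("gc", "sc", TRUE))
})

test_that("attention heatmaps are normalized, sized and deterministic", {
  det <- build_detector(detector_config("gsca"), seed = 2)
  img <- small_scene(seed = 9, n_goats = 2, size = c(160, 160))
  h <- attention_heatmap(det, img, neck_level = 1, input_size = 64)
  expect_equal(dim(h), c(160, 160))
  expect_gte(min(h), 0); expect_lte(max(h), 1)
  h2 <- attention_heatmap(det, img, neck_level = 1, input_size = 64)
  expect_identical(h, h2)
  # constant input runs through the degenerate-range guard
  hz <- attention_heatmap(det, flat_image(160, 160, 0), 1, input_size = 64)
  expect_true(all(is.finite(hz)))
  base <- build_detector(detector_config("baseline"), seed = 1)
  expect_error(attention_heatmap(base, img), "without FPN attention")
  expect_error(attention_heatmap(det, img, neck_level = 9), "neck_level")
})

test_that("detector builds are reproducible and weights round-trip", {
  d1 <- build_detector(detector_config("baseline"), seed = 7)
  d2 <- build_detector(detector_config("baseline"), seed = 7)
  expect_identical(lapply(d1$params, function(p) p$val),
                   lapply(d2$params, function(p) p$val))
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_detector_weights(d1, tmp)
  d3 <- build_detector(detector_config("baseline"), seed = 99)
  load_detector_weights(d3, tmp)
  expect_identical(lapply(d3$params, function(p) p$val),
                   lapply(d1$params, function(p) p$val))
  img <- noisy_image(64, 64, seed = 1)
  expect_identical(predict(d1, img, input_size = 64),
                   predict(d3, img, input_size = 64))
})

test_that("smoke fits are deterministic and finite", {
  imgs <- lapply(1:8, function(i) small_scene(seed = 40 + i, n_goats = 2,
                                              size = c(160, 160)))
  d1 <- build_detector(detector_config("baseline"), seed = 5)
  d2 <- build_detector(detector_config("baseline"), seed = 5)
  f1 <- fit_smoke(d1, imgs, steps = 8, batch_size = 2, input_size = 64,
                  seed = 3)
  f2 <- fit_smoke(d2, imgs, steps = 8, batch_size = 2, input_size = 64,
                  seed = 3)
  expect_identical(f1$loss, f2$loss)
  expect_true(all(is.finite(f1$loss)))
  expect_error(fit_smoke(d1, imgs[1:3]), "at least 8")
})
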