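test_that("IoU matches closed cases and warns on degenerate boxes", {
  b <- data.frame(x1 = 0, y1 = 0, x2 = 2, y2 = 2)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(b, data.frame(x1 = 5, y1 = 5, x2 = 7, y2 = 7)), 0)
  expect_equal(iou(b, data.frame(x1 = 1, y1 = 1, x2 = 3, y2 = 3)), 1 / 7)
  expect_warning(v <- iou(data.frame(x1 = 1, y1 = 1, x2 = 1, y2 = 2), b),
                 "degenerate")
  expect_equal(v, 0)
})

test_that("IoU equals exhaustive pixel enumeration on integer grids", {
  # fully 2-d cell enumeration on a sample of pairs from a 10x10 grid
  iv10 <- all_grid_intervals(10)
  set.seed(42)
  for (k in 1:200) {
    p <- c(iv10[sample(nrow(iv10), 1), ], iv10[sample(nrow(iv10), 1), ])[c(1, 3, 2, 4)]
    t <- c(iv10[sample(nrow(iv10), 1), ], iv10[sample(nrow(iv10), 1), ])[c(1, 3, 2, 4)]
    got <- iou(data.frame(x1 = p[1], y1 = p[2], x2 = p[3], y2 = p[4]),
               data.frame(x1 = t[1], y1 = t[2], x2 = t[3], y2 = t[4]))
    expect_equal(got, enum_iou_2d(p, t, 10))
  }
})

test_that("IoU equals cell counting exhaustively over the 10x10 grid", {
  # every ordered pair of integer boxes in a 10x10 grid, with intersection,
  # and union areas obtained by counting covered unit cells per axis
  iv <- all_grid_intervals(10)
  n <- nrow(iv)  # 55 intervals per axis
  cells <- 0:9
  cover <- sapply(seq_len(n), function(i) cells >= iv[i, 1] & cells < iv[i, 2])
  counts <- colSums(cover)                       # cells covered per interval
  ov <- t(cover) %*% cover                       # pairwise covered-cell overlap
  # enumerate all (pred x-interval, target x-interval, pred y, target y)
  for (i in seq_len(n)) {
    px <- iv[i, ]
    # vectorize over all target x-intervals and all (py, ty) pairs via grid
    grid <- expand.grid(tx = seq_len(n), py = seq_len(n), ty = seq_len(n))
    # evaluate in chunks to bound memory
    pred <- data.frame(x1 = px[1], y1 = iv[grid$py, 1],
                       x2 = px[2], y2 = iv[grid$py, 2])
    targ <- data.frame(x1 = iv[grid$tx, 1], y1 = iv[grid$ty, 1],
                       x2 = iv[grid$tx, 2], y2 = iv[grid$ty, 2])
    got <- iou(pred, targ)
    inter <- ov[i, grid$tx] * ov[cbind(grid$py, grid$ty)]
    un <- counts[i] * counts[grid$py] + counts[grid$tx] * counts[grid$ty] - inter
    expect_equal(got, as.numeric(inter / un), tolerance = 1e-12)
  }
})

test_that("all regression losses vanish on coincident boxes", {
  b <- random_box_table(50, seed = 7)
  for (f in list(ciou_loss, eiou_loss, siou_loss,
                 function(p, t) alpha_ciou_loss(p, t, 3))) {
    expect_equal(f(b, b), rep(0, 50), tolerance = 1e-9)
  }
})

test_that("concentric same-aspect pairs reduce CIoU to 1 - IoU", {
  p <- data.frame(x1 = 10, y1 = 10, x2 = 30, y2 = 20)
  t <- data.frame(x1 = 5, y1 = 7.5, x2 = 35, y2 = 22.5)  # same center, aspect
  expect_equal(ciou_loss(p, t), 1 - iou(p, t), tolerance = 1e-12)
})

test_that("alpha-CIoU equals CIoU at a = 1 and grows with a on partial overlap", {
  p <- random_box_table(200, seed = 11)
  t <- random_box_table(200, seed = 12)
  expect_equal(alpha_ciou_loss(p, t, a = 1), ciou_loss(p, t),
               tolerance = 1e-12)
  # concentric, same aspect, different scale: loss(a=3) > loss(a=1)
  # because iou^3 < iou for iou in (0, 1)
  for (s in c(0.4, 0.6, 0.8)) {
    pp <- data.frame(x1 = -10 * s, y1 = -5 * s, x2 = 10 * s, y2 = 5 * s) + 50
    tt <- data.frame(x1 = 40, y1 = 45, x2 = 60, y2 = 55)
    expect_gt(alpha_ciou_loss(pp, tt, 3), alpha_ciou_loss(pp, tt, 1))
  }
})

test_that("regression losses are invariant to joint translation and scaling", {
  p <- random_box_table(100, seed = 21)
  t <- random_box_table(100, seed = 22)
  shift <- function(b, d) { b[, 1:4] <- b[, 1:4] + d; b }
  scl <- function(b, s) { b[, 1:4] <- b[, 1:4] * s; b }
  for (f in list(ciou_loss, eiou_loss, siou_loss,
                 function(a, b) alpha_ciou_loss(a, b, 3))) {
    base <- f(p, t)
    expect_equal(f(shift(p, 37.5), shift(t, 37.5)), base, tolerance = 1e-8)
    expect_equal(f(scl(p, 4.25), scl(t, 4.25)), base, tolerance = 1e-8)
    expect_true(all(base >= (1 - iou(p, t)) - 1e-12))
  }
})

test_that("losses agree with a straight-line independent reimplementation", {
  # independent scalar re-derivation of the published formulas
  ref <- function(p, t, kind, a = 3) {
    p <- unname(p); t <- unname(t)
    ap <- (p[3] - p[1]) * (p[4] - p[2]); at <- (t[3] - t[1]) * (t[4] - t[2])
    iw <- max(0, min(p[3], t[3]) - max(p[1], t[1]))
    ih <- max(0, min(p[4], t[4]) - max(p[2], t[2]))
    i <- iw * ih / (ap + at - iw * ih)
    pc <- c((p[1] + p[3]) / 2, (p[2] + p[4]) / 2)
    tc <- c((t[1] + t[3]) / 2, (t[2] + t[4]) / 2)
    rho2 <- sum((pc - tc)^2)
    cw <- max(p[3], t[3]) - min(p[1], t[1])
    ch <- max(p[4], t[4]) - min(p[2], t[2])
    c2 <- cw^2 + ch^2 + 1e-9
    pw <- p[3] - p[1]; ph <- p[4] - p[2]; tw <- t[3] - t[1]; th <- t[4] - t[2]
    v <- 4 / pi^2 * (atan(tw / th) - atan(pw / ph))^2
    al <- if (i < 1) v / (1 - i + v + 1e-9) else 0
    if (kind == "ciou") return(1 - i + rho2 / c2 + al * v)
    if (kind == "alpha") return(1 - i^a + (rho2 / c2)^a + (al * v)^a)
    if (kind == "eiou") {
      return(1 - i + rho2 / c2 + (pw - tw)^2 / (cw^2 + 1e-9) +
               (ph - th)^2 / (ch^2 + 1e-9))
    }
    # siou
    sigma <- sqrt(rho2) + 1e-9
    sin_a <- min(abs(tc[2] - pc[2]) / sigma, 1)
    Lam <- 2 * sin_a * sqrt(max(0, 1 - sin_a^2))
    gam <- 2 - Lam
    rx <- ((tc[1] - pc[1]) / (cw + 1e-9))^2
    ry <- ((tc[2] - pc[2]) / (ch + 1e-9))^2
    Del <- (1 - exp(-gam * rx)) + (1 - exp(-gam * ry))
    ww <- abs(pw - tw) / max(pw, tw); wh <- abs(ph - th) / max(ph, th)
    Om <- (1 - exp(-ww))^4 + (1 - exp(-wh))^4
    1 - i + (Del + Om) / 2
  }
  p <- random_box_table(1000, seed = 31)
  t <- random_box_table(1000, seed = 32)
  pm <- as.matrix(p[, 1:4]); tm <- as.matrix(t[, 1:4])
  for (k in seq_len(1000)) {
    expect_equal(ciou_loss(p[k, ], t[k, ]), ref(pm[k, ], tm[k, ], "ciou"),
                 tolerance = 1e-9)
  }
  ks <- seq(1, 1000, by = 10)
  for (k in ks) {
    expect_equal(eiou_loss(p[k, ], t[k, ]), ref(pm[k, ], tm[k, ], "eiou"),
                 tolerance = 1e-9)
    expect_equal(siou_loss(p[k, ], t[k, ]), ref(pm[k, ], tm[k, ], "siou"),
                 tolerance = 1e-9)
    expect_equal(alpha_ciou_loss(p[k, ], t[k, ], 3),
                 ref(pm[k, ], tm[k, ], "alpha"), tolerance = 1e-9)
  }
})

test_that("distribution focal loss matches hand-computed cross-entropy", {
  # one-hot logits with a large margin: loss tends to 0
  z <- rep(-20, 16); z[6] <- 20
  expect_lt(dfl_loss(z, 5), 1e-8)
  # midway target weights the two bins equally
  z2 <- rep(0, 16)
  expect_equal(dfl_loss(z2, 4.5), -log(1 / 16))
  # arbitrary case vs scalar hand computation
  set.seed(13)
  z3 <- rnorm(16)
  t3 <- 7.3
  p <- exp(z3) / sum(exp(z3))
  hand <- -(0.7 * log(p[8]) + 0.3 * log(p[9]))
  expect_equal(dfl_loss(z3, t3), hand, tolerance = 1e-9)
  expect_warning(dfl_loss(z3, 20), "clamped")
})

test_that("classification loss has its closed-form floors", {
  z <- matrix(c(50, -50), 1)
  t <- matrix(c(1, 0), 1)
  expect_lt(cls_loss(z, t), 1e-8)
  z0 <- matrix(0, 4, 4)
  t0 <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(cls_loss(z0, t0), log(2))
  set.seed(14)
  z1 <- matrix(rnorm(12), 3); t1 <- matrix(runif(12), 3)
  hand <- mean(-(t1 * log(plogis(z1)) + (1 - t1) * log(1 - plogis(z1))))
  expect_equal(cls_loss(z1, t1), hand, tolerance = 1e-9)
  expect_error(cls_loss(z1, t1[1:2, ]), "shapes")
})

test_that("the differentiable box loss agrees with the plain implementations", {
  tp <- caprimon:::new_tape()
  set.seed(15)
  P <- 40
  p <- random_box_table(P, 20, 20, seed = 41)
  t <- random_box_table(P, 20, 20, seed = 42)
  pm <- as.matrix(p[, 1:4]); tm <- as.matrix(t[, 1:4])
  pb <- caprimon:::tape_node(tp, pm, 1L, 1L, 4L, P)
  for (kind in c("iou", "ciou", "eiou", "siou", "alpha_ciou")) {
    nd <- caprimon:::tape_box_loss_sum(tp, pb, tm, kind, alpha = 3)
    plain <- switch(kind, iou = sum(1 - iou(p, t)),
                    ciou = sum(ciou_loss(p, t)),
                    eiou = sum(eiou_loss(p, t)),
                    siou = sum(siou_loss(p, t)),
                    alpha_ciou = sum(alpha_ciou_loss(p, t, 3)))
    expect_equal(nd$val[1], plain, tolerance = 1e-6,
                 info = paste("kind", kind))
  }
})

test_that("switching the box loss kind changes only the box component", {
  imgs <- lapply(1:2, function(i) small_scene(seed = i, n_goats = 2,
                                              size = c(160, 160)))
  det <- build_detector(detector_config("baseline"), seed = 3)
  a <- total_loss(det, imgs, box_loss_kind = "ciou", input_size = 64)
  b <- total_loss(det, imgs, box_loss_kind = "siou", input_size = 64)
  expect_equal(a$cls_loss, b$cls_loss)
  expect_equal(a$dfl_loss, b$dfl_loss)
  expect_false(isTRUE(all.equal(a$box_loss, b$box_loss)))
  w <- loss_weights()
  expect_equal(a$total, w[["box"]] * a$box_loss + w[["dfl"]] * a$dfl_loss +
                 w[["cls"]] * a$cls_loss, tolerance = 1e-9)
})
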