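# Target assignment, the differentiable training objective, and the
# desk-scale smoke trainer.

const_node <- function(tp, m) tape_node(tp, m, 1L, 1L, ncol(m), nrow(m))

# Center-prior top-k assignment: candidate anchors are those whose point
# falls inside a ground-truth box (across all three scales); each truth
# keeps its k closest candidates, and an anchor claimed by several truths
# goes to the closest one. Static (prediction-independent), hence stable
# for short smoke fits.
assign_targets <- function(gt, scale_dims, strides, reg_max, topk = 10) {
  anch <- do.call(rbind, lapply(seq_along(strides), function(s) {
    H <- scale_dims[[s]][1]; W <- scale_dims[[s]][2]; st <- strides[s]
    xs <- rep(seq_len(W), times = H)
    ys <- rep(seq_len(H), each = W)
    data.frame(scale = s, row = xs + (ys - 1L) * W,
               cx = (xs - 0.5) * st, cy = (ys - 0.5) * st, stride = st)
  }))
  n_gt <- nrow(gt)
  if (n_gt == 0) return(NULL)
  pick_gt <- integer(0); pick_anchor <- integer(0); pick_d <- numeric(0)
  for (g in seq_len(n_gt)) {
    inside <- which(anch$cx > gt$x1[g] & anch$cx < gt$x2[g] &
                      anch$cy > gt$y1[g] & anch$cy < gt$y2[g])
    if (!length(inside)) next
    gcx <- (gt$x1[g] + gt$x2[g]) / 2; gcy <- (gt$y1[g] + gt$y2[g]) / 2
    d <- (anch$cx[inside] - gcx)^2 + (anch$cy[inside] - gcy)^2
    keep <- inside[order(d)[seq_len(min(topk, length(inside)))]]
    pick_gt <- c(pick_gt, rep(g, length(keep)))
    pick_anchor <- c(pick_anchor, keep)
    pick_d <- c(pick_d, sort(d)[seq_len(length(keep))])
  }
  if (!length(pick_anchor)) return(NULL)
  # resolve conflicts: anchor goes to the closest truth
  o <- order(pick_anchor, pick_d)
  first <- !duplicated(pick_anchor[o])
  sel <- o[first]
  a <- pick_anchor[sel]; g <- pick_gt[sel]
  st <- anch$stride[a]
  dist <- cbind((anch$cx[a] - gt$x1[g]) / st, (anch$cy[a] - gt$y1[g]) / st,
                (gt$x2[g] - anch$cx[a]) / st, (gt$y2[g] - anch$cy[a]) / st)
  dist <- pmin(pmax(dist, 0), reg_max - 1 - 0.01)
  data.frame(scale = anch$scale[a], row = anch$row[a],
             cx = anch$cx[a], cy = anch$cy[a], stride = st,
             gx1 = gt$x1[g], gy1 = gt$y1[g], gx2 = gt$x2[g], gy2 = gt$y2[g],
             dl = dist[, 1], dt = dist[, 2], dr = dist[, 3], db = dist[, 4],
             cls = class_index(gt$cls[g]) + 1L)
}

# differentiable box regression loss (sum over rows) built from tape
# primitives; `pb` holds predicted corners in grid units, `tmat` targets
tape_box_loss_sum <- function(tp, pb, tmat, kind, alpha = 3) {
  eps <- 1e-9
  cn <- function(j) const_node(tp, tmat[, j, drop = FALSE])
  px1 <- ew_col(tp, pb, 1); py1 <- ew_col(tp, pb, 2)
  px2 <- ew_col(tp, pb, 3); py2 <- ew_col(tp, pb, 4)
  tx1 <- cn(1); ty1 <- cn(2); tx2 <- cn(3); ty2 <- cn(4)
  iw <- ew_clamp_min(tp, ew_sub(tp, ew_min2(tp, px2, tx2),
                                ew_max2(tp, px1, tx1)), 0)
  ih <- ew_clamp_min(tp, ew_sub(tp, ew_min2(tp, py2, ty2),
                                ew_max2(tp, py1, ty1)), 0)
  inter <- ew_mul(tp, iw, ih)
  pw <- ew_clamp_min(tp, ew_sub(tp, px2, px1), eps)
  ph <- ew_clamp_min(tp, ew_sub(tp, py2, py1), eps)
  tw <- ew_clamp_min(tp, ew_sub(tp, tx2, tx1), eps)
  th <- ew_clamp_min(tp, ew_sub(tp, ty2, ty1), eps)
  un <- ew_sub(tp, ew_add(tp, ew_mul(tp, pw, ph), ew_mul(tp, tw, th)), inter)
  i <- ew_div(tp, inter, ew_addc(tp, un, eps))
  one_m_iou <- ew_addc(tp, ew_mulc(tp, i, -1), 1)
  if (kind == "iou") return(ew_mulc(tp, ew_mean(tp, one_m_iou), nrow(tmat)))
  pcx <- ew_mulc(tp, ew_add(tp, px1, px2), 0.5)
  pcy <- ew_mulc(tp, ew_add(tp, py1, py2), 0.5)
  tcx <- ew_mulc(tp, ew_add(tp, tx1, tx2), 0.5)
  tcy <- ew_mulc(tp, ew_add(tp, ty1, ty2), 0.5)
  dx <- ew_sub(tp, pcx, tcx); dy <- ew_sub(tp, pcy, tcy)
  rho2 <- ew_add(tp, ew_mul(tp, dx, dx), ew_mul(tp, dy, dy))
  cw <- ew_sub(tp, ew_max2(tp, px2, tx2), ew_min2(tp, px1, tx1))
  ch <- ew_sub(tp, ew_max2(tp, py2, ty2), ew_min2(tp, py1, ty1))
  c2 <- ew_addc(tp, ew_add(tp, ew_mul(tp, cw, cw), ew_mul(tp, ch, ch)), eps)
  dc <- ew_div(tp, rho2, c2)
  per_row <- switch(
    kind,
    ciou = , alpha_ciou = {
      dratio <- ew_sub(tp, ew_atan(tp, ew_div(tp, tw, th)),
                       ew_atan(tp, ew_div(tp, pw, ph)))
      v <- ew_mulc(tp, ew_mul(tp, dratio, dratio), 4 / pi^2)
      alpha_const <- ifelse(i$val < 1, v$val / ((1 - i$val) + v$val + eps), 0)
      av <- ew_mul(tp, v, const_node(tp, alpha_const))
      if (kind == "ciou") {
        ew_add(tp, ew_add(tp, one_m_iou, dc), av)
      } else {
        t1 <- ew_addc(tp, ew_mulc(tp, ew_pow(tp, ew_clamp_min(tp, i, 0),
                                             alpha), -1), 1)
        ew_add(tp, ew_add(tp, t1, ew_pow(tp, dc, alpha)),
               ew_pow(tp, ew_clamp_min(tp, av, 0), alpha))
      }
    },
    eiou = {
      dw <- ew_sub(tp, pw, tw); dh <- ew_sub(tp, ph, th)
      tw2 <- ew_div(tp, ew_mul(tp, dw, dw),
                    ew_addc(tp, ew_mul(tp, cw, cw), eps))
      th2 <- ew_div(tp, ew_mul(tp, dh, dh),
                    ew_addc(tp, ew_mul(tp, ch, ch), eps))
      ew_add(tp, ew_add(tp, ew_add(tp, one_m_iou, dc), tw2), th2)
    },
    siou = {
      sigma <- ew_addc(tp, ew_sqrt(tp, rho2), eps)
      sin_a <- ew_div(tp, ew_abs(tp, ew_sub(tp, tcy, pcy)), sigma)
      cos_a <- ew_sqrt(tp, ew_clamp_min(
        tp, ew_addc(tp, ew_mulc(tp, ew_mul(tp, sin_a, sin_a), -1), 1), 0))
      lambda <- ew_mulc(tp, ew_mul(tp, sin_a, cos_a), 2)
      gamma <- ew_addc(tp, ew_mulc(tp, lambda, -1), 2)
      rx <- ew_mul(tp, ew_div(tp, dx, ew_addc(tp, cw, eps)),
                   ew_div(tp, dx, ew_addc(tp, cw, eps)))
      ry <- ew_mul(tp, ew_div(tp, dy, ew_addc(tp, ch, eps)),
                   ew_div(tp, dy, ew_addc(tp, ch, eps)))
      dterm <- ew_sub(tp, ew_const(tp, rx, 2),
                      ew_add(tp, ew_exp(tp, ew_mulc(tp, ew_mul(tp, gamma, rx), -1)),
                             ew_exp(tp, ew_mulc(tp, ew_mul(tp, gamma, ry), -1))))
      ww <- ew_div(tp, ew_abs(tp, ew_sub(tp, pw, tw)), ew_max2(tp, pw, tw))
      wh <- ew_div(tp, ew_abs(tp, ew_sub(tp, ph, th)), ew_max2(tp, ph, th))
      om <- ew_add(
        tp,
        ew_pow(tp, ew_addc(tp, ew_mulc(tp, ew_exp(tp, ew_mulc(tp, ww, -1)), -1), 1), 4),
        ew_pow(tp, ew_addc(tp, ew_mulc(tp, ew_exp(tp, ew_mulc(tp, wh, -1)), -1), 1), 4))
      ew_add(tp, one_m_iou, ew_mulc(tp, ew_add(tp, dterm, om), 0.5))
    },
    stop("unknown box loss kind '", kind, "'", call. = FALSE))
  ew_mulc(tp, ew_mean(tp, per_row), nrow(tmat))
}

# Build the full training objective for one forward pass.
# `gt_list`: one box table per image, in letterboxed-canvas coordinates.
detection_loss <- function(fw, gt_list, config, weights = loss_weights(),
                           box_loss_kind = "ciou", alpha = 3) {
  tp <- fw$tape
  outs <- fw$outputs
  nimg <- fw$n
  reg_max <- config$reg_max
  nc <- config$nc
  strides <- vapply(outs, function(o) o$stride, 0L)
  scale_dims <- lapply(outs, function(o) c(o$H, o$W))
  # per-scale accumulators
  cls_targets <- lapply(outs, function(o)
    matrix(0, o$H * o$W * nimg, nc))
  pos <- lapply(seq_along(outs), function(s)
    list(rows = integer(), dist = NULL, tbox = NULL))
  n_pos <- 0L
  for (im in seq_len(nimg)) {
    asg <- assign_targets(gt_list[[im]], scale_dims, strides, reg_max)
    if (is.null(asg)) next
    for (s in seq_along(outs)) {
      sub <- asg[asg$scale == s, , drop = FALSE]
      if (!nrow(sub)) next
      off <- (im - 1L) * outs[[s]]$H * outs[[s]]$W
      rows <- off + sub$row
      cls_targets[[s]][cbind(rows, sub$cls)] <- 1
      st <- sub$stride
      tbox <- cbind(sub$gx1, sub$gy1, sub$gx2, sub$gy2) / st  # grid units
      pos[[s]]$rows <- c(pos[[s]]$rows, rows)
      pos[[s]]$dist <- rbind(pos[[s]]$dist,
                             cbind(sub$dl, sub$dt, sub$dr, sub$db))
      pos[[s]]$tbox <- rbind(pos[[s]]$tbox, tbox)
      n_pos <- n_pos + nrow(sub)
    }
  }
  # classification: element-count weighted mean BCE across scales
  n_el <- vapply(outs, function(o) o$H * o$W * nimg * nc, 0)
  cls_parts <- lapply(seq_along(outs), function(s)
    op_bce_loss(tp, outs[[s]]$cls, cls_targets[[s]]))
  cls_node <- ew_weighted_sum_scalar(tp, cls_parts, n_el / sum(n_el))
  if (n_pos > 0) {
    box_parts <- list(); dfl_parts <- list(); wts <- numeric(0)
    for (s in seq_along(outs)) {
      if (!length(pos[[s]]$rows)) next
      sel <- op_gather_rows(tp, outs[[s]]$box, pos[[s]]$rows)
      dists <- op_dfl_expect(tp, sel, reg_max)
      P <- length(pos[[s]]$rows)
      hw <- outs[[s]]$H; ww <- outs[[s]]$W
      # anchor centers in grid units for these rows
      r0 <- (pos[[s]]$rows - 1L) %% (hw * ww)
      ax <- (r0 %% ww) + 0.5
      ay <- (r0 %/% ww) + 0.5
      amat <- cbind(ax, ay, ax, ay)
      smat <- matrix(c(-1, -1, 1, 1), P, 4, byrow = TRUE)
      pb <- ew_add(tp, const_node(tp, amat),
                   ew_mul(tp, dists, const_node(tp, smat)))
      box_parts[[length(box_parts) + 1L]] <-
        tape_box_loss_sum(tp, pb, pos[[s]]$tbox, box_loss_kind, alpha)
      dfl_parts[[length(dfl_parts) + 1L]] <-
        ew_mulc(tp, op_dfl_loss(tp, sel, pos[[s]]$dist, reg_max), P)
      wts <- c(wts, 1)
    }
    box_node <- ew_weighted_sum_scalar(tp, box_parts,
                                       rep(1 / n_pos, length(box_parts)))
    dfl_node <- ew_weighted_sum_scalar(tp, dfl_parts,
                                       rep(1 / n_pos, length(dfl_parts)))
  } else {
    box_node <- const_node(tp, matrix(0, 1, 1))
    dfl_node <- const_node(tp, matrix(0, 1, 1))
  }
  total <- ew_weighted_sum_scalar(
    tp, list(box_node, dfl_node, cls_node),
    c(weights[["box"]], weights[["dfl"]], weights[["cls"]]))
  list(total = total,
       breakdown = list(box_loss = box_node$val[1], dfl_loss = dfl_node$val[1],
                        cls_loss = cls_node$val[1], total = total$val[1],
                        weights = weights, n_pos = n_pos))
}

#' Total detection loss breakdown
#'
#' Runs the detector on annotated images (letterboxed to `input_size`),
#' assigns targets with the center-prior top-k assigner, and evaluates the
#' weighted training objective: an IoU-family box loss, the distribution
#' focal loss, and binary cross-entropy classification. With no positive
#' assignments the box and distribution terms are 0 and only the
#' classification floor remains.
#'
#' @param detector a `goat_detector`.
#' @param images list of [annotated_image()] with ground-truth boxes.
#' @param weights a [loss_weights()] vector.
#' @param box_loss_kind `"iou"`, `"ciou"`, `"eiou"`, `"siou"` or
#'   `"alpha_ciou"`.
#' @param a Alpha-CIoU power.
#' @param input_size square network input side (divisible by 32).
#' @return A list with `box_loss`, `dfl_loss`, `cls_loss`, `total`,
#'   `weights` and `n_pos`; `total` is the weighted sum of the components.
#' @export
total_loss <- function(detector, images, weights = loss_weights(),
                       box_loss_kind = "ciou", a = 3, input_size = 64) {
  prep <- .letterbox_batch(images, input_size)
  fw <- forward_detector(detector, prep$imgs, training = FALSE)
  dl <- detection_loss(fw, prep$gt, detector$config, weights, box_loss_kind, a)
  dl$breakdown
}

.letterbox_batch <- function(images, input_size) {
  imgs <- list(); gt <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    stopifnot(inherits(im, "annotated_image"))
    lb <- letterbox(im$pixels, input_size)
    imgs[[i]] <- lb$canvas
    gt[[i]] <- boxes_to_canvas(im$boxes, lb)
  }
  list(imgs = imgs, gt = gt)
}

#' Adam optimizer settings
#'
#' @param lr learning rate (default 0.001).
#' @param weight_decay L2 regularization coefficient (default 1e-5), applied
#'   to convolution/dense weights only (not biases or batch-norm terms).
#' @param beta1,beta2,eps Adam moment parameters.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(lr = 0.001, weight_decay = 1e-5, beta1 = 0.9,
                             beta2 = 0.999, eps = 1e-8) {
  structure(list(lr = lr, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, eps = eps), class = "optimizer_config")
}

.adam_step <- function(params, opt, t) {
  for (p in params) {
    g <- as.vector(p$grad)
    if (p$decay && opt$weight_decay > 0) g <- g + opt$weight_decay * as.vector(p$val)
    if (is.null(p$m)) { p$m <- numeric(length(g)); p$v <- numeric(length(g)) }
    p$m <- opt$beta1 * p$m + (1 - opt$beta1) * g
    p$v <- opt$beta2 * p$v + (1 - opt$beta2) * g * g
    mhat <- p$m / (1 - opt$beta1^t)
    vhat <- p$v / (1 - opt$beta2^t)
    p$val <- p$val - array(opt$lr * mhat / (sqrt(vhat) + opt$eps),
                           dim = dim(p$val))
    p$grad[] <- 0
  }
}

#' Smoke-train a detector on a small synthetic set
#'
#' Runs a short optimization (Adam, default lr 0.001, weight decay 1e-5,
#' mixup augmentation on) on a handful of annotated images — enough to
#' verify that the full assignment/loss/backprop path optimizes, not to
#' reach deployment accuracy. Images are letterboxed to a small square
#' input so the run stays desk-scale.
#'
#' @param detector a `goat_detector` (updated in place).
#' @param dataset list of at least 8 [annotated_image()] objects.
#' @param steps number of optimizer steps (`<= 500`).
#' @param optimizer an [optimizer_config()].
#' @param batch_size images per step.
#' @param input_size square input side (divisible by 32).
#' @param box_loss_kind box loss; `NULL` uses the variant default
#'   (`alpha_ciou` for the named lightweight variants, `ciou` otherwise).
#' @param use_mixup blend half of the batches pairwise with
#'   `lam ~ U(0.4, 0.6)`.
#' @param seed RNG seed for batching and mixup.
#' @return An object of class `goat_fit` with the per-step loss trace.
#' @export
fit_smoke <- function(detector, dataset, steps = 200,
                      optimizer = optimizer_config(), batch_size = 4,
                      input_size = 64, box_loss_kind = NULL,
                      use_mixup = TRUE, seed = 0) {
  stopifnot(inherits(detector, "goat_detector"))
  if (!is.list(dataset) || length(dataset) < 8) {
    stop("fit_smoke needs a dataset of at least 8 annotated images",
         call. = FALSE)
  }
  stopifnot(steps >= 1, steps <= 500)
  if (is.null(box_loss_kind)) {
    box_loss_kind <- if (detector$config$variant == "baseline") "ciou" else
      "alpha_ciou"
  }
  trace <- numeric(steps)
  comps <- matrix(0, steps, 3,
                  dimnames = list(NULL, c("box", "dfl", "cls")))
  with_seed(seed, {
    for (t in seq_len(steps)) {
      take <- sample(length(dataset), batch_size,
                     replace = batch_size > length(dataset))
      batch <- dataset[take]
      if (use_mixup && batch_size >= 2 && stats::runif(1) < 0.5) {
        j <- sample(batch_size, 2)
        batch[[j[1]]] <- mixup(batch[[j[1]]], batch[[j[2]]],
                               lam = stats::runif(1, 0.4, 0.6))
      }
      prep <- .letterbox_batch(batch, input_size)
      fw <- forward_detector(detector, prep$imgs, training = TRUE)
      dl <- detection_loss(fw, prep$gt, detector$config,
                           box_loss_kind = box_loss_kind)
      if (!is.finite(dl$breakdown$total)) {
        stop("non-finite loss at step ", t, call. = FALSE)
      }
      tape_backward(fw$tape, dl$total)
      .adam_step(detector$params, optimizer, t)
      trace[t] <- dl$breakdown$total
      comps[t, ] <- c(dl$breakdown$box_loss, dl$breakdown$dfl_loss,
                      dl$breakdown$cls_loss)
    }
  })
  structure(list(loss = trace, components = comps, steps = steps,
                 optimizer = optimizer, box_loss_kind = box_loss_kind,
                 detector = detector), class = "goat_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.goat_fit <- function(x, ...) {
  n <- min(10, x$steps)
  cat(sprintf("<goat_fit> %d steps, box loss '%s'\n", x$steps, x$box_loss_kind))
  cat(sprintf("  mean total loss: first %d steps %.4f -> last %d steps %.4f\n",
              n, mean(x$loss[seq_len(n)]), n,
              mean(x$loss[(x$steps - n + 1):x$steps])))
  invisible(x)
}

#' @export
plot.goat_fit <- function(x, ...) {
  graphics::plot(seq_len(x$steps), x$loss, type = "l", xlab = "step",
                 ylab = "total loss", main = "smoke-fit loss trace", ...)
  invisible(x)
}
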