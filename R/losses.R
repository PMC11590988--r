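.pair_mats <- function(pred, target) {
  p <- as.matrix(as.data.frame(pred)[, c("x1", "y1", "x2", "y2")])
  t <- as.matrix(as.data.frame(target)[, c("x1", "y1", "x2", "y2")])
  if (nrow(p) != nrow(t)) stop("pred and target must pair row-wise",
                               call. = FALSE)
  list(p = p, t = t)
}

#' Intersection over union of paired boxes
#'
#' Row-wise IoU of two box tables in the same coordinate frame:
#' intersection area over union area, 0 for disjoint pairs. A degenerate
#' (zero-area) box yields 0 with a warning.
#'
#' @param pred,target box tables (or matrices with columns `x1, y1, x2, y2`)
#'   of equal row count.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
#' @examples
#' iou(data.frame(x1 = 0, y1 = 0, x2 = 2, y2 = 2),
#'     data.frame(x1 = 1, y1 = 1, x2 = 3, y2 = 3))  # 1/7
iou <- function(pred, target) {
  m <- .pair_mats(pred, target)
  ap <- (m$p[, 3] - m$p[, 1]) * (m$p[, 4] - m$p[, 2])
  at <- (m$t[, 3] - m$t[, 1]) * (m$t[, 4] - m$t[, 2])
  if (any(ap <= 0) || any(at <= 0)) {
    warning("degenerate zero-area box; IoU set to 0")
  }
  iw <- pmax(0, pmin(m$p[, 3], m$t[, 3]) - pmax(m$p[, 1], m$t[, 1]))
  ih <- pmax(0, pmin(m$p[, 4], m$t[, 4]) - pmax(m$p[, 2], m$t[, 2]))
  inter <- iw * ih
  un <- ap + at - inter
  out <- ifelse(un > 0 & ap > 0 & at > 0, inter / un, 0)
  as.numeric(pmax(0, pmin(1, out)))
}

# shared geometric terms of the IoU penalty family
.reg_terms <- function(pred, target, eps = 1e-9) {
  m <- .pair_mats(pred, target)
  p <- m$p; t <- m$t
  pw <- pmax(p[, 3] - p[, 1], eps); ph <- pmax(p[, 4] - p[, 2], eps)
  tw <- pmax(t[, 3] - t[, 1], eps); th <- pmax(t[, 4] - t[, 2], eps)
  pcx <- (p[, 1] + p[, 3]) / 2; pcy <- (p[, 2] + p[, 4]) / 2
  tcx <- (t[, 1] + t[, 3]) / 2; tcy <- (t[, 2] + t[, 4]) / 2
  cw <- pmax(p[, 3], t[, 3]) - pmin(p[, 1], t[, 1])
  ch <- pmax(p[, 4], t[, 4]) - pmin(p[, 2], t[, 2])
  i <- suppressWarnings(iou(p, t))
  v <- (4 / pi^2) * (atan(tw / th) - atan(pw / ph))^2
  alpha_c <- ifelse(i < 1, v / ((1 - i) + v + eps), 0)
  list(iou = i, pw = pw, ph = ph, tw = tw, th = th, pcx = pcx, pcy = pcy,
       tcx = tcx, tcy = tcy, cw = cw, ch = ch,
       rho2 = (pcx - tcx)^2 + (pcy - tcy)^2, c2 = cw^2 + ch^2 + eps,
       v = v, alpha_c = alpha_c, eps = eps)
}

#' IoU-family bounding-box regression losses
#'
#' Row-wise regression losses between paired predicted and target boxes.
#' All are 0 iff the boxes coincide and are invariant to joint translation
#' and joint uniform scaling of each pair:
#'
#' * `ciou_loss`: `1 - IoU + rho^2/c^2 + alpha_c * v`, with `rho` the center
#'   distance, `c` the enclosing-box diagonal, `v` the aspect-ratio
#'   consistency term, and `alpha_c = v / ((1 - IoU) + v)` its trade-off.
#' * `eiou_loss`: `1 - IoU + rho^2/c^2 + (w - w_t)^2/c_w^2 +
#'   (h - h_t)^2/c_h^2` over the enclosing-box width and height.
#' * `siou_loss`: `1 - IoU + (distance_cost + shape_cost)/2` with the
#'   angle-modulated distance cost of the SIoU formulation.
#' * `alpha_ciou_loss`: `1 - IoU^a + (rho^2/c^2)^a + (alpha_c * v)^a`;
#'   `a = 1` recovers `ciou_loss` exactly, the default power is `a = 3`.
#'
#' @param pred,target paired box tables.
#' @param a positive power of the Alpha-CIoU loss.
#' @return Numeric vector of non-negative losses.
#' @export
ciou_loss <- function(pred, target) {
  g <- .reg_terms(pred, target)
  as.numeric(1 - g$iou + g$rho2 / g$c2 + g$alpha_c * g$v)
}

#' @rdname ciou_loss
#' @export
eiou_loss <- function(pred, target) {
  g <- .reg_terms(pred, target)
  as.numeric(1 - g$iou + g$rho2 / g$c2 +
               (g$pw - g$tw)^2 / (g$cw^2 + g$eps) +
               (g$ph - g$th)^2 / (g$ch^2 + g$eps))
}

#' @rdname ciou_loss
#' @export
siou_loss <- function(pred, target) {
  g <- .reg_terms(pred, target)
  sigma <- sqrt(g$rho2) + g$eps
  sin_a <- pmin(abs(g$tcy - g$pcy) / sigma, 1)
  lambda <- 2 * sin_a * sqrt(pmax(1 - sin_a^2, 0))   # sin(2*arcsin(x))
  gamma <- 2 - lambda
  rx <- ((g$tcx - g$pcx) / (g$cw + g$eps))^2
  ry <- ((g$tcy - g$pcy) / (g$ch + g$eps))^2
  delta <- (1 - exp(-gamma * rx)) + (1 - exp(-gamma * ry))
  ww <- abs(g$pw - g$tw) / pmax(g$pw, g$tw)
  wh <- abs(g$ph - g$th) / pmax(g$ph, g$th)
  omega <- (1 - exp(-ww))^4 + (1 - exp(-wh))^4
  as.numeric(1 - g$iou + (delta + omega) / 2)
}

#' @rdname ciou_loss
#' @export
alpha_ciou_loss <- function(pred, target, a = 3) {
  stopifnot(a > 0)
  g <- .reg_terms(pred, target)
  as.numeric(1 - g$iou^a + (g$rho2 / g$c2)^a + (g$alpha_c * g$v)^a)
}

#' Distribution focal loss
#'
#' Cross-entropy of a discrete distribution over `reg_max` distance bins
#' against the two integer bins bracketing a continuous target `t`:
#' the left bin `l = floor(t)` is weighted `(l + 1 - t)` and the right bin
#' `(t - l)`. Targets outside `[0, reg_max - 1]` are clamped with a warning.
#'
#' @param bin_logits numeric matrix (rows = targets, `reg_max` columns) or a
#'   single logit vector.
#' @param target continuous bin-unit targets, one per row.
#' @return Mean loss over targets (non-negative).
#' @export
dfl_loss <- function(bin_logits, target) {
  if (is.null(dim(bin_logits))) bin_logits <- matrix(bin_logits, nrow = 1)
  reg_max <- ncol(bin_logits)
  if (any(target < 0 | target > reg_max - 1)) {
    warning("DFL target outside [0, reg_max - 1]; clamped")
    target <- pmin(pmax(target, 0), reg_max - 1)
  }
  t <- pmin(target, reg_max - 1 - 1e-9)
  l <- floor(t); r <- l + 1
  wl <- r - t; wr <- t - l
  z <- bin_logits - apply(bin_logits, 1, max)
  logp <- z - log(rowSums(exp(z)))
  i <- seq_len(nrow(bin_logits))
  mean(-(wl * logp[cbind(i, l + 1)] + wr * logp[cbind(i, pmin(r + 1, reg_max))]))
}

#' Classification loss
#'
#' Mean binary cross-entropy with logits over classes and positions,
#' accepting hard 0/1 or soft targets.
#'
#' @param class_logits numeric matrix of per-class logits.
#' @param targets matrix of the same shape with values in `[0, 1]`.
#' @return Mean loss (non-negative).
#' @export
cls_loss <- function(class_logits, targets) {
  z <- as.matrix(class_logits); t <- as.matrix(targets)
  if (!all(dim(z) == dim(t))) stop("logit and target shapes differ",
                                   call. = FALSE)
  mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
}

.box_loss_fun <- function(kind, alpha = 3) {
  switch(kind,
         iou = function(p, t) 1 - iou(p, t),
         ciou = ciou_loss,
         eiou = eiou_loss,
         siou = siou_loss,
         alpha_ciou = function(p, t) alpha_ciou_loss(p, t, a = alpha),
         stop("unknown box loss kind '", kind, "'", call. = FALSE))
}

#' Loss weighting scheme
#'
#' Default component weights of the total detection objective: box 7.5,
#' distribution-regression 1.5, classification 0.5.
#'
#' @param box,dfl,cls non-negative component weights.
#' @return Named numeric vector.
#' @export
loss_weights <- function(box = 7.5, dfl = 1.5, cls = 0.5) {
  c(box = box, dfl = dfl, cls = cls)
}
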