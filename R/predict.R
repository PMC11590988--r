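#' Evaluation protocol
#'
#' The confidence and non-maximum-suppression thresholds used when decoding
#' detections: confidence 0.001 and NMS IoU 0.5 for evaluation; deployment
#' uses a higher confidence cut.
#'
#' @param conf_threshold confidence threshold in (0, 1).
#' @param nms_iou NMS IoU threshold in (0, 1).
#' @return An `eval_protocol` list.
#' @export
eval_protocol <- function(conf_threshold = 0.001, nms_iou = 0.5) {
  stopifnot(conf_threshold > 0, conf_threshold < 1, nms_iou > 0, nms_iou < 1)
  structure(list(conf_threshold = conf_threshold, nms_iou = nms_iou),
            class = "eval_protocol")
}

#' Class-wise greedy non-maximum suppression
#'
#' Detections are processed per class in order of descending confidence
#' (ties broken by lower row index); a detection is suppressed when its IoU
#' with an already kept same-class detection exceeds the threshold.
#'
#' @param det box data frame with `conf` set.
#' @param nms_iou IoU threshold.
#' @return The surviving subset of `det`.
#' @export
nms_boxes <- function(det, nms_iou = 0.5) {
  if (!nrow(det)) return(det)
  keep_all <- logical(nrow(det))
  for (cl in unique(det$cls)) {
    idx <- which(det$cls == cl)
    ord <- idx[order(-det$conf[idx], idx)]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept)) {
        ious <- box_iou_matrix(det[i, , drop = FALSE],
                               det[kept, , drop = FALSE])
        if (any(ious > nms_iou)) next
      }
      kept <- c(kept, i)
    }
    keep_all[kept] <- TRUE
  }
  out <- det[keep_all, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# decode raw head maps for one image (rows already restricted to it) into
# candidate boxes in canvas pixels
.decode_scale <- function(box_raw, cls_raw, H, W, stride, reg_max, conf_thr) {
  nc <- ncol(cls_raw)
  conf <- 1 / (1 + exp(-cls_raw))
  best <- max.col(conf, ties.method = "first")
  best_conf <- conf[cbind(seq_len(nrow(conf)), best)]
  sel <- which(best_conf >= conf_thr)
  if (!length(sel)) return(empty_boxes())
  dists <- matrix(0, length(sel), 4)
  bins <- 0:(reg_max - 1)
  for (s in 1:4) {
    cols <- (s - 1L) * reg_max + seq_len(reg_max)
    z <- box_raw[sel, cols, drop = FALSE]
    z <- z - apply(z, 1, max)
    e <- exp(z)
    dists[, s] <- (e / rowSums(e)) %*% bins
  }
  r0 <- sel - 1L
  ax <- (r0 %% W) + 0.5
  ay <- (r0 %/% W) + 0.5
  data.frame(x1 = (ax - dists[, 1]) * stride, y1 = (ay - dists[, 2]) * stride,
             x2 = (ax + dists[, 3]) * stride, y2 = (ay + dists[, 4]) * stride,
             cls = behavior_classes()[best[sel]], conf = best_conf[sel],
             stringsAsFactors = FALSE)
}

#' Detect goats in images
#'
#' Full inference path: letterbox to a square input, forward pass,
#' distribution decoding (expected bin value times stride around each
#' anchor point), confidence filtering, class-wise greedy NMS, and mapping
#' of the surviving boxes back to source-image coordinates.
#'
#' @param object a `goat_detector`.
#' @param images a raster, an [annotated_image()], or a list of either.
#' @param protocol an [eval_protocol()].
#' @param input_size square network input (divisible by 32).
#' @param ... unused.
#' @return A box data frame (single image) or list of box data frames, with
#'   `conf` filled in. An empty table is a valid result.
#' @export
predict.goat_detector <- function(object, images, protocol = eval_protocol(),
                                  input_size = 640, ...) {
  single <- FALSE
  if (inherits(images, "annotated_image") ||
      (is.array(images) && length(dim(images)) == 3)) {
    images <- list(images)
    single <- TRUE
  }
  px <- lapply(images, function(im)
    if (inherits(im, "annotated_image")) im$pixels else im)
  out <- vector("list", length(px))
  reg_max <- object$config$reg_max
  for (i in seq_along(px)) {
    lb <- letterbox(px[[i]], input_size)
    fw <- forward_detector(object, list(lb$canvas), training = FALSE)
    cand <- do.call(rbind, lapply(fw$outputs, function(o)
      .decode_scale(o$box$val, o$cls$val, o$H, o$W, o$stride, reg_max,
                    protocol$conf_threshold)))
    if (is.null(cand) || !nrow(cand)) {
      out[[i]] <- empty_boxes()
      next
    }
    cand <- clip_boxes(cand, 0, 0, lb$target, lb$target)
    cand <- nms_boxes(cand, protocol$nms_iou)
    out[[i]] <- boxes_to_source(cand, lb)
  }
  if (single) out[[1]] else out
}

#' Attention heatmap of a neck level
#'
#' Channel-mean of the post-attention activation at one of the three neck
#' levels, bilinearly upsampled to the input size and min-max normalized to
#' `[0, 1]`. Requires a detector built with `fpn_attention != "none"`.
#'
#' @param detector a `goat_detector`.
#' @param image raster or [annotated_image()].
#' @param neck_level 1 (stride 8), 2 (stride 16) or 3 (stride 32).
#' @param input_size square network input.
#' @return `H x W` numeric matrix in `[0, 1]` (source-image size).
#' @export
attention_heatmap <- function(detector, image, neck_level = 1,
                              input_size = 640) {
  stopifnot(inherits(detector, "goat_detector"))
  if (detector$config$fpn_attention == "none") {
    stop("detector was built without FPN attention", call. = FALSE)
  }
  if (!neck_level %in% 1:3) stop("neck_level must be 1, 2 or 3", call. = FALSE)
  px <- if (inherits(image, "annotated_image")) image$pixels else image
  lb <- letterbox(px, input_size)
  fw <- forward_detector(detector, list(lb$canvas), training = FALSE)
  nd <- fw$neck[[neck_level]]
  amap <- matrix(rowMeans(nd$val), nd$H, nd$W, byrow = TRUE)
  up <- resize_bilinear(amap, lb$target, lb$target)
  # crop the content region and map back to source size
  d <- raster_dim(px)
  cw <- round(d$w * lb$scale); chh <- round(d$h * lb$scale)
  up <- up[(lb$pad_y + 1):(lb$pad_y + chh), (lb$pad_x + 1):(lb$pad_x + cw),
           drop = FALSE]
  up <- resize_bilinear(up, d$h, d$w)
  rng <- range(up)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, d$h, d$w))
  (up - rng[1]) / (rng[2] - rng[1])
}
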