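#' Vertical stitching augmentation
#'
#' Stacks two equally wide annotated frames vertically. Unlike mosaic, no
#' box is cropped, dropped or resized: top boxes are unchanged and bottom
#' boxes are translated down by the top image's height, so two standard
#' 1280 x 720 monitoring frames become one 1280 x 1440 composite whose
#' aspect ratio is closer to the square detector input (see
#' [gray_fill_fraction()]). `horizontal_stitch()` is the symmetric operator
#' for equally tall frames, with the same conservation contract.
#'
#' @param top,bottom [annotated_image()] objects of identical width.
#' @return An [annotated_image()] of size `W x (H_top + H_bottom)`.
#' @export
vertical_stitch <- function(top, bottom) {
  stopifnot(inherits(top, "annotated_image"), inherits(bottom, "annotated_image"))
  if (top$width != bottom$width) {
    stop("vertical_stitch requires equal widths (got ", top$width, " and ",
         bottom$width, "); no implicit resizing is performed", call. = FALSE)
  }
  h <- top$height + bottom$height
  px <- array(0, dim = c(h, top$width, 3))
  px[1:top$height, , ] <- top$pixels
  px[(top$height + 1):h, , ] <- bottom$pixels
  b <- rbind(top$boxes, shift_boxes(bottom$boxes, 0, top$height))
  annotated_image(px, b, source_id = paste0(top$source_id, "+", bottom$source_id))
}

#' @rdname vertical_stitch
#' @param left,right [annotated_image()] objects of identical height.
#' @export
horizontal_stitch <- function(left, right) {
  stopifnot(inherits(left, "annotated_image"), inherits(right, "annotated_image"))
  if (left$height != right$height) {
    stop("horizontal_stitch requires equal heights (got ", left$height,
         " and ", right$height, ")", call. = FALSE)
  }
  w <- left$width + right$width
  px <- array(0, dim = c(left$height, w, 3))
  px[, 1:left$width, ] <- left$pixels
  px[, (left$width + 1):w, ] <- right$pixels
  b <- rbind(left$boxes, shift_boxes(right$boxes, left$width, 0))
  annotated_image(px, b, source_id = paste0(left$source_id, "+", right$source_id))
}

#' Mosaic parameters
#'
#' @param out_size `c(W, H)` of the composite.
#' @param scale_range `c(lo, hi)` multiplicative scale range in `(0, 2]`.
#' @param min_box_area_frac boxes whose clipped area falls below this
#'   fraction of their scaled pre-clip area are dropped (in `[0, 1]`),
#'   reproducing the label-loss phenomenon of mosaic on occluded herds.
#'   Default 0.25; 1 keeps only boxes that survive uncut.
#' @param seed integer RNG seed.
#' @return A `mosaic_params` list.
#' @export
mosaic_params <- function(out_size = c(640, 640), scale_range = c(0.5, 1.5),
                          min_box_area_frac = 0.25, seed = 1) {
  stopifnot(length(out_size) == 2, all(out_size > 0),
            scale_range[1] <= scale_range[2], scale_range[1] > 0,
            scale_range[2] <= 2,
            min_box_area_frac >= 0, min_box_area_frac <= 1)
  structure(list(out_size = as.integer(out_size),
                 scale_range = as.numeric(scale_range),
                 min_box_area_frac = min_box_area_frac,
                 seed = as.integer(seed)), class = "mosaic_params")
}

#' Mosaic augmentation
#'
#' Randomly scales four images and stitches them into a 2 x 2 composite
#' around a seeded random center split. Each tile is cropped to its
#' quadrant; boxes are transformed and clipped accordingly, and a box whose
#' clipped area falls below `min_box_area_frac` of its original area is
#' dropped (mosaic can cut animals in half, losing labels).
#'
#' @param four_images list of exactly four [annotated_image()] objects.
#' @param params a [mosaic_params()].
#' @return An [annotated_image()] of size `out_size`.
#' @export
mosaic <- function(four_images, params = mosaic_params()) {
  if (!is.list(four_images) || length(four_images) != 4) {
    stop("mosaic takes exactly four annotated images", call. = FALSE)
  }
  stopifnot(inherits(params, "mosaic_params"))
  w <- params$out_size[1]; h <- params$out_size[2]
  with_seed(params$seed, {
    cx <- round(stats::runif(1, 0.25, 0.75) * w)
    cy <- round(stats::runif(1, 0.25, 0.75) * h)
    # quadrant windows: (x1, y1, x2, y2) in composite coordinates
    quads <- list(c(0, 0, cx, cy), c(cx, 0, w, cy),
                  c(0, cy, cx, h), c(cx, cy, w, h))
    px <- array(114, dim = c(h, w, 3))
    out_boxes <- list()
    for (q in 1:4) {
      im <- four_images[[q]]
      stopifnot(inherits(im, "annotated_image"))
      sc <- stats::runif(1, params$scale_range[1], params$scale_range[2])
      sw <- max(1, round(im$width * sc)); sh <- max(1, round(im$height * sc))
      scaled <- resize_bilinear(im$pixels, sh, sw)
      qx1 <- quads[[q]][1]; qy1 <- quads[[q]][2]
      qx2 <- quads[[q]][3]; qy2 <- quads[[q]][4]
      qw <- qx2 - qx1; qh <- qy2 - qy1
      if (qw < 1 || qh < 1) next
      # anchor each tile at the shared center corner
      ox <- if (q %in% c(1, 3)) qx2 - sw else qx1
      oy <- if (q %in% c(1, 2)) qy2 - sh else qy1
      sx1 <- max(qx1, ox); sy1 <- max(qy1, oy)
      sx2 <- min(qx2, ox + sw); sy2 <- min(qy2, oy + sh)
      if (sx2 > sx1 && sy2 > sy1) {
        px[(sy1 + 1):sy2, (sx1 + 1):sx2, ] <-
          scaled[(sy1 - oy + 1):(sy2 - oy), (sx1 - ox + 1):(sx2 - ox), ]
      }
      b <- im$boxes
      if (nrow(b)) {
        b <- shift_boxes(scale_boxes(b, sw / im$width, sh / im$height), ox, oy)
        scaled_area <- box_area(b)
        # clip to the quadrant without dropping, then apply the area rule
        b$x1 <- pmax(b$x1, qx1); b$y1 <- pmax(b$y1, qy1)
        b$x2 <- pmin(b$x2, qx2); b$y2 <- pmin(b$y2, qy2)
        clip_area <- pmax(0, b$x2 - b$x1) * pmax(0, b$y2 - b$y1)
        keep <- clip_area > 0 & clip_area >= params$min_box_area_frac * scaled_area
        b <- b[keep, , drop = FALSE]
        rownames(b) <- NULL
      }
      out_boxes[[q]] <- b
    }
    bb <- do.call(rbind, out_boxes)
    if (is.null(bb)) bb <- empty_boxes()
    rownames(bb) <- NULL
    annotated_image(px, bb, source_id = "mosaic")
  })
}

#' Mixup augmentation
#'
#' Blends two equally sized annotated images pixel-wise,
#' `lam * a + (1 - lam) * b` (rounded to 8-bit), and takes the union of both
#' label sets untouched.
#'
#' @param a,b [annotated_image()] objects of identical size.
#' @param lam mixing weight in `[0, 1]`.
#' @return An [annotated_image()].
#' @export
mixup <- function(a, b, lam = 0.5) {
  stopifnot(inherits(a, "annotated_image"), inherits(b, "annotated_image"),
            lam >= 0, lam <= 1)
  if (a$width != b$width || a$height != b$height) {
    stop("mixup requires equally sized images", call. = FALSE)
  }
  px <- round(lam * a$pixels + (1 - lam) * b$pixels)
  annotated_image(px, rbind(a$boxes, b$boxes),
                  source_id = paste0("mixup(", a$source_id, ",", b$source_id, ")"))
}
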