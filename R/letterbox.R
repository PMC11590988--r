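#' Letterbox an image onto a square canvas
#'
#' Aspect-preserving resize by `scale = min(target/W, target/H)`, centered on
#' a `target x target` canvas filled with gray value 114 — the square input
#' format the detector's preprocessing expects. The returned transform maps
#' canvas coordinates back to source coordinates (and vice versa); composing
#' the two is the identity within a pixel.
#'
#' @param img `H x W x 3` raster.
#' @param target canvas side length in pixels.
#' @return A list with `canvas` (the letterboxed raster), `scale`, `pad_x`,
#'   `pad_y` (left/top padding in canvas pixels), `src_size = c(W, H)`, and
#'   `target`.
#' @export
#' @examples
#' lb <- letterbox(new_raster(720, 1280, 100), 640)
#' lb$scale; lb$pad_y   # 0.5, 140
letterbox <- function(img, target = 640) {
  d <- raster_dim(img)
  stopifnot(target >= 1)
  scale <- min(target / d$w, target / d$h)
  new_w <- round(d$w * scale); new_h <- round(d$h * scale)
  resized <- resize_bilinear(img, new_h, new_w)
  canvas <- new_raster(target, target, 114)
  pad_x <- floor((target - new_w) / 2)
  pad_y <- floor((target - new_h) / 2)
  canvas[(pad_y + 1):(pad_y + new_h), (pad_x + 1):(pad_x + new_w), ] <- resized
  list(canvas = canvas, scale = scale, pad_x = pad_x, pad_y = pad_y,
       src_size = c(d$w, d$h), target = target)
}

#' @rdname letterbox
#' @param b box data frame in source coordinates.
#' @param lb a letterbox transform as returned by [letterbox()].
#' @export
boxes_to_canvas <- function(b, lb) {
  shift_boxes(scale_boxes(b, lb$scale), lb$pad_x, lb$pad_y)
}

#' @rdname letterbox
#' @export
boxes_to_source <- function(b, lb) {
  b <- shift_boxes(b, -lb$pad_x, -lb$pad_y)
  b <- scale_boxes(b, 1 / lb$scale)
  clip_boxes(b, 0, 0, lb$src_size[1], lb$src_size[2])
}

#' Fraction of the letterboxed canvas occupied by gray padding
#'
#' For an image fitted aspect-preservingly onto a `target x target` canvas,
#' the fraction of canvas area that is padding rather than content. Square
#' inputs need no padding; the fraction grows as the aspect ratio departs
#' from 1.
#'
#' @param image_size `c(W, H)` in pixels.
#' @param target canvas side length.
#' @return Padding fraction in `[0, 1)`.
#' @export
#' @examples
#' gray_fill_fraction(c(1280, 720))   # 0.4375
#' gray_fill_fraction(c(1280, 1440))  # smaller: closer to square
gray_fill_fraction <- function(image_size, target = 640) {
  w <- image_size[1]; h <- image_size[2]
  stopifnot(w > 0, h > 0, target >= 1)
  scale <- min(target / w, target / h)
  content <- round(w * scale) * round(h * scale)
  1 - content / target^2
}
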