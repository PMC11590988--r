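#' Annotated images
#'
#' An `annotated_image` couples an RGB raster with its bounding-box table and
#' provenance. It is the unit that flows through enhancement, augmentation,
#' detection and the monitoring pipeline.
#'
#' @param pixels `H x W x 3` raster (8-bit values in `[0, 255]`).
#' @param boxes box data frame (see [boxes()]); must lie within the image.
#' @param source_id character identifier of the originating camera/file.
#' @param timestamp optional `POSIXct` wall-clock time.
#' @return An object of class `annotated_image` with elements `pixels`,
#'   `boxes`, `source_id`, `timestamp`, `width`, `height`.
#' @export
annotated_image <- function(pixels, boxes = empty_boxes(),
                            source_id = "unknown", timestamp = NULL) {
  d <- raster_dim(pixels)
  b <- validate_boxes(boxes, width = d$w, height = d$h)
  structure(list(pixels = pixels, boxes = b, source_id = source_id,
                 timestamp = timestamp, width = d$w, height = d$h),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image> %dx%d px, %d box(es), source '%s'\n",
              x$width, x$height, nrow(x$boxes), x$source_id))
  if (nrow(x$boxes)) print(table(x$boxes$cls))
  invisible(x)
}

#' @export
#' @rdname annotated_image
#' @param x an `annotated_image`.
#' @param box_col border color for boxes.
#' @param ... passed on to [graphics::rasterImage()] machinery.
plot.annotated_image <- function(x, box_col = "yellow", ...) {
  img <- clamp8(x$pixels) / 255
  graphics::plot(c(0, x$width), c(0, x$height), type = "n", asp = 1,
                 xlab = "", ylab = "", axes = FALSE,
                 main = x$source_id)
  graphics::rasterImage(img, 0, 0, x$width, x$height, ...)
  if (nrow(x$boxes)) {
    graphics::rect(x$boxes$x1, x$height - x$boxes$y2,
                   x$boxes$x2, x$height - x$boxes$y1,
                   border = box_col, lwd = 2)
    graphics::text(x$boxes$x1, x$height - x$boxes$y1, labels = x$boxes$cls,
                   adj = c(0, -0.3), col = box_col, cex = 0.8)
  }
  invisible(x)
}
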