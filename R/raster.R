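#' Raster helpers
#'
#' Images are stored as numeric arrays of shape `H x W x 3` holding 8-bit
#' values in `[0, 255]` (row = image row, from the top). PNG is the on-disk
#' format; [read_image()]/[write_image()] convert between the two.
#'
#' @param h,w image height and width in pixels.
#' @param value fill value (a single gray level or length-3 RGB).
#' @return `new_raster()`: an `H x W x 3` array.
#' @export
new_raster <- function(h, w, value = 0) {
  stopifnot(h >= 1, w >= 1)
  if (length(value) == 1) value <- rep(value, 3)
  arr <- array(0, dim = c(h, w, 3))
  for (k in 1:3) arr[, , k] <- value[k]
  arr
}

raster_dim <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) < 2) stop("not an image array", call. = FALSE)
  list(h = d[1], w = d[2], ch = if (length(d) >= 3) d[3] else 1L)
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)  # order keeps dim attributes

#' @rdname new_raster
#' @param path PNG file path.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' @rdname new_raster
#' @param img an `H x W x 3` raster.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp8(img) / 255, path)
  invisible(path)
}

#' @rdname new_raster
#' @export
luminance <- function(img) {
  d <- dim(img)
  if (is.null(d) || length(d) == 2) return(as.matrix(img))
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear resize of an H x W (x C) raster to out_h x out_w.
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  two_d <- length(d) == 2
  if (two_d) img <- array(img, dim = c(d, 1))
  d <- dim(img)
  h <- d[1]; w <- d[2]; nc <- d[3]
  # align-corners = FALSE convention: sample at pixel centers
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(out_h, out_w, nc))
  for (k in seq_len(nc)) {
    ch <- img[, , k]
    a <- ch[y0 + 1, x0 + 1, drop = FALSE]
    b <- ch[y0 + 1, x1 + 1, drop = FALSE]
    cc <- ch[y1 + 1, x0 + 1, drop = FALSE]
    dd <- ch[y1 + 1, x1 + 1, drop = FALSE]
    wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
    wym <- matrix(wy, out_h, out_w)
    top <- a * (1 - wxm) + b * wxm
    bot <- cc * (1 - wxm) + dd * wxm
    out[, , k] <- top * (1 - wym) + bot * wym
  }
  if (two_d) out[, , 1] else out
}

# Evaluate code with a private RNG stream; global .Random.seed is restored.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
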