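#' Bounding-box tables
#'
#' Boxes are plain data frames with columns `x1, y1, x2, y2` (pixel corners,
#' 0-based half-open intervals: a box covers `[x1, x2) x [y1, y2)`), `cls`
#' (one of [behavior_classes()]) and `conf` (detection confidence in `[0, 1]`,
#' `NA` for ground truth). `boxes()` builds and validates such a table.
#'
#' @param x1,y1,x2,y2 numeric corner coordinates, `x1 < x2`, `y1 < y2`.
#' @param cls character behavior classes (synonyms accepted).
#' @param conf optional numeric confidences in `[0, 1]`.
#' @return A `data.frame` with columns `x1, y1, x2, y2, cls, conf`.
#' @export
#' @examples
#' boxes(10, 20, 30, 60, "eat")
boxes <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                  y2 = numeric(), cls = character(), conf = NULL) {
  n <- length(x1)
  if (is.null(conf)) conf <- rep(NA_real_, n)
  b <- data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
                  x2 = as.numeric(x2), y2 = as.numeric(y2),
                  cls = if (n) normalize_class(cls) else character(),
                  conf = as.numeric(conf), stringsAsFactors = FALSE)
  validate_boxes(b)
}

#' @rdname boxes
#' @param b a box data frame.
#' @param width,height optional image extent; when given, boxes must lie
#'   within `[0, width] x [0, height]`.
#' @export
validate_boxes <- function(b, width = NULL, height = NULL) {
  stopifnot(is.data.frame(b))
  need <- c("x1", "y1", "x2", "y2", "cls")
  if (!all(need %in% names(b))) {
    stop("box table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"conf" %in% names(b)) b$conf <- NA_real_
  b <- b[, c("x1", "y1", "x2", "y2", "cls", "conf")]
  if (nrow(b) == 0) return(b)
  co <- as.matrix(b[, 1:4])
  if (any(!is.finite(co))) stop("box coordinates must be finite", call. = FALSE)
  if (any(co < 0)) stop("box coordinates must be >= 0", call. = FALSE)
  if (any(b$x2 <= b$x1) || any(b$y2 <= b$y1)) {
    stop("boxes must have x1 < x2 and y1 < y2", call. = FALSE)
  }
  b$cls <- normalize_class(b$cls)
  ok <- is.na(b$conf) | (b$conf >= 0 & b$conf <= 1)
  if (!all(ok)) stop("confidences must lie in [0, 1]", call. = FALSE)
  if (!is.null(width)) {
    if (any(b$x2 > width + 1e-6) || any(b$y2 > height + 1e-6)) {
      stop("box extends beyond the image (", width, "x", height, ")",
           call. = FALSE)
    }
  }
  rownames(b) <- NULL
  b
}

empty_boxes <- function() boxes()

box_area <- function(b) pmax(0, b$x2 - b$x1) * pmax(0, b$y2 - b$y1)

shift_boxes <- function(b, dx, dy) {
  if (nrow(b)) {
    b$x1 <- b$x1 + dx; b$x2 <- b$x2 + dx
    b$y1 <- b$y1 + dy; b$y2 <- b$y2 + dy
  }
  b
}

scale_boxes <- function(b, sx, sy = sx) {
  if (nrow(b)) {
    b$x1 <- b$x1 * sx; b$x2 <- b$x2 * sx
    b$y1 <- b$y1 * sy; b$y2 <- b$y2 * sy
  }
  b
}

# Clip to a window; rows reduced to zero area are dropped.
clip_boxes <- function(b, x1, y1, x2, y2) {
  if (!nrow(b)) return(b)
  b$x1 <- pmax(b$x1, x1); b$y1 <- pmax(b$y1, y1)
  b$x2 <- pmin(b$x2, x2); b$y2 <- pmin(b$y2, y2)
  keep <- b$x2 > b$x1 & b$y2 > b$y1
  b <- b[keep, , drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Pairwise intersection-over-union of two box tables
#'
#' @param a,b box data frames (or 4-column matrices `x1, y1, x2, y2`).
#' @return `nrow(a) x nrow(b)` matrix of IoU values.
#' @export
box_iou_matrix <- function(a, b) {
  am <- as.matrix(as.data.frame(a)[, c("x1", "y1", "x2", "y2")])
  bm <- as.matrix(as.data.frame(b)[, c("x1", "y1", "x2", "y2")])
  na <- nrow(am); nb <- nrow(bm)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ix1 <- pmax(matrix(am[, 1], na, nb), matrix(bm[, 1], na, nb, byrow = TRUE))
  iy1 <- pmax(matrix(am[, 2], na, nb), matrix(bm[, 2], na, nb, byrow = TRUE))
  ix2 <- pmin(matrix(am[, 3], na, nb), matrix(bm[, 3], na, nb, byrow = TRUE))
  iy2 <- pmin(matrix(am[, 4], na, nb), matrix(bm[, 4], na, nb, byrow = TRUE))
  inter <- pmax(0, ix2 - ix1) * pmax(0, iy2 - iy1)
  aa <- (am[, 3] - am[, 1]) * (am[, 4] - am[, 2])
  ab <- (bm[, 3] - bm[, 1]) * (bm[, 4] - bm[, 2])
  un <- matrix(aa, na, nb) + matrix(ab, na, nb, byrow = TRUE) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}
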