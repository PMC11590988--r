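#' Synthetic pen-scene configuration
#'
#' Describes a top-down view of a housed-goat pen: a textured floor, a feed
#' trough strip along the top edge, a water point in the bottom-right corner,
#' and `n_goats` goat-like blobs whose pose encodes their behavior class
#' (lying: low-aspect blob; stand: elongated blob with a shadow; eat: blob
#' overlapping the trough; drink: blob overlapping the water point).
#'
#' The default class mix is proportional to the 8418-label split of the
#' behavior dataset the generator emulates (4415 lying / 2869 standing /
#' 112 drinking / 1022 eating). Density regimes translate the stocking rates
#' of 2 m2/goat (high) and 3 m2/goat (low) into pixel area at a fixed scale
#' of 60 px/m.
#'
#' @param image_size `c(W, H)` in pixels.
#' @param n_goats number of goats to place.
#' @param density `"high"` (2 m2/goat) or `"low"` (3 m2/goat).
#' @param lighting `"day"` or `"night"` (night applies [degrade_night()]).
#' @param class_mix probability vector over `lying, stand, drink, eat`;
#'   must sum to 1.
#' @param occlusion_level maximum allowed IoU between goat body boxes during
#'   placement, in `[0, 1]`.
#' @param box_mode `"amodal"` boxes cover the full drawn extent of each goat
#'   (as annotators box partially hidden animals); `"visible"` shrinks them
#'   to the pixels left visible after later goats are drawn on top.
#' @param seed integer; fully determines the output.
#' @return A `pen_scene_config` list.
#' @export
pen_scene_config <- function(image_size = c(1280, 720), n_goats = 12,
                             density = c("high", "low"),
                             lighting = c("day", "night"),
                             class_mix = c(4415, 2869, 112, 1022) / 8418,
                             occlusion_level = 0.3,
                             box_mode = c("amodal", "visible"),
                             seed = 1) {
  density <- match.arg(density)
  lighting <- match.arg(lighting)
  box_mode <- match.arg(box_mode)
  stopifnot(length(image_size) == 2, all(image_size > 0), n_goats >= 0,
            occlusion_level >= 0, occlusion_level <= 1)
  if (abs(sum(class_mix) - 1) > 1e-9) {
    stop("class_mix must sum to 1", call. = FALSE)
  }
  structure(list(image_size = as.integer(image_size), n_goats = as.integer(n_goats),
                 density = density, lighting = lighting,
                 class_mix = as.numeric(class_mix),
                 occlusion_level = occlusion_level, box_mode = box_mode,
                 seed = as.integer(seed), px_per_m = 60),
            class = "pen_scene_config")
}

# pen layout in pixels
.pen_layout <- function(config) {
  w <- config$image_size[1]; h <- config$image_size[2]
  trough_h <- max(6, round(0.07 * h))
  water_r <- max(8, round(0.05 * min(w, h)))
  list(w = w, h = h, trough_h = trough_h,
       water_cx = w - water_r * 1.2, water_cy = h - water_r * 1.2,
       water_r = water_r)
}

# Rotated-ellipse half extents along x and y.
.ellipse_extent <- function(a, b, theta) {
  c(sqrt((a * cos(theta))^2 + (b * sin(theta))^2),
    sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
}

# Sample goat states (class, position, orientation, size) with bounded-retry
# rejection on pairwise overlap. Pure given the active RNG stream.
.place_goats <- function(config) {
  lay <- .pen_layout(config)
  ppm <- config$px_per_m
  area_per_goat <- switch(config$density, high = 2, low = 3) * ppm^2
  free_area <- lay$w * (lay$h - lay$trough_h)
  if (config$n_goats * area_per_goat > free_area) {
    stop("cannot place ", config$n_goats, " goats at density '",
         config$density, "' in a ", lay$w, "x", lay$h, " pen", call. = FALSE)
  }
  states <- vector("list", config$n_goats)
  if (!config$n_goats) return(states)
  cls_all <- sample(behavior_classes(), config$n_goats, replace = TRUE,
                    prob = config$class_mix)
  placed <- matrix(numeric(0), 0, 4)
  for (i in seq_len(config$n_goats)) {
    st <- NULL
    for (try in 1:200) {
      cand <- .sample_goat_state(cls_all[i], lay, ppm)
      bb <- cand$body_box
      ok <- TRUE
      if (nrow(placed)) {
        iou <- box_iou_matrix(
          data.frame(x1 = bb[1], y1 = bb[2], x2 = bb[3], y2 = bb[4]),
          data.frame(x1 = placed[, 1], y1 = placed[, 2],
                     x2 = placed[, 3], y2 = placed[, 4]))
        ok <- all(iou <= config$occlusion_level)
      }
      if (ok) { st <- cand; break }
    }
    if (is.null(st)) {
      stop("placement failed for goat ", i, " after bounded retries; ",
           "lower n_goats or raise occlusion_level", call. = FALSE)
    }
    placed <- rbind(placed, st$body_box)
    states[[i]] <- st
  }
  states
}

.sample_goat_state <- function(cls, lay, ppm) {
  body_a <- 0.5 * ppm * stats::runif(1, 0.85, 1.1)   # semi length ~30 px
  body_b <- 0.2 * ppm * stats::runif(1, 0.85, 1.15)  # semi width ~12 px
  shade <- stats::runif(1, 0.8, 1.0)                 # coat brightness factor
  if (cls == "lying") {
    a <- body_a * 0.8; b <- body_b * 1.6
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, a, lay$w - a)
    cy <- stats::runif(1, lay$trough_h + b, lay$h - b)
  } else if (cls == "stand") {
    a <- body_a; b <- body_b
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, a, lay$w - a)
    cy <- stats::runif(1, lay$trough_h + b, lay$h - b)
  } else if (cls == "eat") {
    a <- body_a; b <- body_b
    theta <- pi / 2 + stats::rnorm(1, 0, 0.08)       # head-up into the trough
    cx <- stats::runif(1, b + 2, lay$w - b - 2)
    cy <- lay$trough_h + a * stats::runif(1, 0.35, 0.6)  # overlaps the strip
  } else {                                           # drink
    a <- body_a; b <- body_b
    ang <- stats::runif(1, pi * 0.9, pi * 1.45)      # approach from inside
    cx <- lay$water_cx + cos(ang) * lay$water_r * 1.1
    cy <- lay$water_cy + sin(ang) * lay$water_r * 1.1
    theta <- atan2(lay$water_cy - cy, lay$water_cx - cx)
    cx <- min(max(cx, a), lay$w - 2)
    cy <- min(max(cy, a), lay$h - 2)
  }
  ext <- .ellipse_extent(a, b, theta)
  head_r <- b * 0.6
  hx <- cx + cos(theta) * (a + head_r * 0.6)
  hy <- cy + sin(theta) * (a + head_r * 0.6)
  x1 <- min(cx - ext[1], hx - head_r); x2 <- max(cx + ext[1], hx + head_r)
  y1 <- min(cy - ext[2], hy - head_r); y2 <- max(cy + ext[2], hy + head_r)
  list(cls = cls, cx = cx, cy = cy, a = a, b = b, theta = theta,
       head = c(hx, hy, head_r), shade = shade,
       body_box = c(cx - ext[1], cy - ext[2], cx + ext[1], cy + ext[2]),
       full_box = c(x1, y1, x2, y2))
}

.fill_ellipse <- function(canvas, idmask, cx, cy, a, b, theta, color, id) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  ext <- .ellipse_extent(a, b, theta)
  xs <- max(1, floor(cx - ext[1])):min(w, ceiling(cx + ext[1]))
  ys <- max(1, floor(cy - ext[2])):min(h, ceiling(cy + ext[2]))
  if (!length(xs) || !length(ys)) return(list(canvas = canvas, idmask = idmask))
  dx <- matrix(xs - 0.5 - cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - 0.5 - cy, length(ys), length(xs))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- (u^2 + v^2) <= 1
  if (!any(inside)) return(list(canvas = canvas, idmask = idmask))
  for (k in 1:3) {
    ch <- canvas[ys, xs, k]
    ch[inside] <- color[k]
    canvas[ys, xs, k] <- ch
  }
  sub <- idmask[ys, xs]
  sub[inside] <- id
  idmask[ys, xs] <- sub
  list(canvas = canvas, idmask = idmask)
}

.render_scene <- function(states, config) {
  lay <- .pen_layout(config)
  h <- lay$h; w <- lay$w
  base <- c(152, 140, 118)
  canvas <- new_raster(h, w, base)
  tex <- matrix(stats::rnorm(h * w, 0, 6), h, w)
  for (k in 1:3) canvas[, , k] <- canvas[, , k] + tex
  canvas[1:lay$trough_h, , 1] <- 108
  canvas[1:lay$trough_h, , 2] <- 88
  canvas[1:lay$trough_h, , 3] <- 66
  idmask <- matrix(0L, h, w)
  res <- .fill_ellipse(canvas, idmask, lay$water_cx, lay$water_cy,
                       lay$water_r, lay$water_r, 0, c(66, 108, 160), 0L)
  canvas <- res$canvas; idmask <- res$idmask
  for (i in seq_along(states)) {
    st <- states[[i]]
    coat <- 228 * st$shade
    if (st$cls == "stand") {
      res <- .fill_ellipse(canvas, idmask, st$cx + 4, st$cy + 4,
                           st$a, st$b, st$theta, base * 0.55, 0L)
      canvas <- res$canvas; idmask <- res$idmask
    }
    res <- .fill_ellipse(canvas, idmask, st$cx, st$cy, st$a, st$b, st$theta,
                         rep(coat, 3), i)
    canvas <- res$canvas; idmask <- res$idmask
    hd <- st$head
    res <- .fill_ellipse(canvas, idmask, hd[1], hd[2], hd[3], hd[3], 0,
                         rep(coat * 0.82, 3), i)
    canvas <- res$canvas; idmask <- res$idmask
  }
  canvas <- clamp8(round(canvas))
  if (length(states)) {
    if (config$box_mode == "visible") {
      bl <- lapply(seq_along(states), function(i) {
        hit <- which(idmask == i, arr.ind = TRUE)
        if (!nrow(hit)) return(NULL)
        c(min(hit[, 2]) - 1, min(hit[, 1]) - 1, max(hit[, 2]), max(hit[, 1]),
          i)
      })
      bl <- bl[!vapply(bl, is.null, TRUE)]
      m <- do.call(rbind, bl)
      b <- boxes(m[, 1], m[, 2], m[, 3], m[, 4],
                 vapply(states[m[, 5]], `[[`, "", "cls"))
    } else {
      m <- do.call(rbind, lapply(states, `[[`, "full_box"))
      b <- data.frame(x1 = pmax(0, m[, 1]), y1 = pmax(0, m[, 2]),
                      x2 = pmin(w, m[, 3]), y2 = pmin(h, m[, 4]),
                      cls = vapply(states, `[[`, "", "cls"),
                      conf = NA_real_)
      b <- validate_boxes(b, width = w, height = h)
    }
  } else {
    b <- empty_boxes()
  }
  if (config$lighting == "night") {
    canvas <- degrade_night(canvas, gamma = 2.2, noise_sigma = 4)
  }
  annotated_image(canvas, b, source_id = sprintf("pen-seed%d", config$seed))
}

#' Generate a synthetic annotated pen image
#'
#' Renders a deterministic top-down pen scene from a [pen_scene_config()],
#' with one ground-truth box per goat whose pose encodes its behavior class.
#' The same seed always produces a bit-identical image and box table.
#'
#' @param config a [pen_scene_config()].
#' @return An [annotated_image()].
#' @export
#' @examples
#' img <- generate_pen_image(pen_scene_config(c(320, 240), n_goats = 4, seed = 7))
#' img$boxes
generate_pen_image <- function(config) {
  stopifnot(inherits(config, "pen_scene_config"))
  with_seed(config$seed, .render_scene(.place_goats(config), config))
}

#' Degrade an image to night-time conditions
#'
#' Compresses luminance with a gamma curve (`gamma > 1` darkens) and adds
#' Gaussian sensor noise, emulating the poor contrast of pen cameras at
#' night. With `noise_sigma = 0` the gray-level histogram is compressed, so
#' discrete entropy cannot increase.
#'
#' @param img `H x W x 3` raster (or matrix) of 8-bit values.
#' @param gamma darkening exponent, `>= 1`.
#' @param noise_sigma standard deviation of additive Gaussian noise, `>= 0`.
#' @return Degraded raster of the same shape, 8-bit.
#' @export
degrade_night <- function(img, gamma = 2.2, noise_sigma = 4) {
  stopifnot(gamma >= 1, noise_sigma >= 0)
  out <- 255 * (clamp8(img) / 255)^gamma
  if (noise_sigma > 0) {
    out <- out + stats::rnorm(length(out), 0, noise_sigma)
  }
  clamp8(round(out))
}

#' Generate a synthetic pen video with ground-truth records
#'
#' Produces a coherent frame sequence from a seeded pen scene. Between
#' seconds, each goat independently switches behavior with probability
#' `motion` (re-sampling class from the configured mix and re-placing it);
#' frames within a second are identical. Alongside the frames, the per-second
#' ground-truth behavior-record stream is returned.
#'
#' @param config a [pen_scene_config()].
#' @param n_seconds video length in seconds.
#' @param fps frames per second, `>= 1`.
#' @param motion per-second probability that a goat switches behavior.
#' @param start_time `POSIXct` stamp of the first second.
#' @return A list with `frames` (list of [annotated_image()], length
#'   `n_seconds * fps`), `records` (ground-truth [behavior_records()], one row
#'   per second), `fps`, and `config`.
#' @export
generate_video <- function(config, n_seconds, fps = 1, motion = 0.1,
                           start_time = as.POSIXct("2023-10-08 09:15:03",
                                                   tz = "UTC")) {
  stopifnot(inherits(config, "pen_scene_config"), fps >= 1, n_seconds >= 0,
            motion >= 0, motion <= 1)
  with_seed(config$seed, {
    states <- .place_goats(config)
    frames <- vector("list", n_seconds * fps)
    recs <- vector("list", n_seconds)
    for (s in seq_len(n_seconds)) {
      if (s > 1 && length(states)) {
        for (i in seq_along(states)) {
          if (stats::runif(1) < motion) {
            lay <- .pen_layout(config)
            cls <- sample(behavior_classes(), 1, prob = config$class_mix)
            states[[i]] <- .sample_goat_state(cls, lay, config$px_per_m)
          }
        }
      }
      scene <- .render_scene(states, config)
      tt <- start_time + (s - 1)
      scene$timestamp <- tt
      for (f in seq_len(fps)) frames[[(s - 1) * fps + f]] <- scene
      cls <- if (length(states)) vapply(states, `[[`, "", "cls") else character()
      recs[[s]] <- data.frame(
        date = as.Date(tt, tz = "UTC"),
        time = format(tt, "%H:%M:%S", tz = "UTC"),
        standing = sum(cls == "stand"), drinking = sum(cls == "drink"),
        lying_down = sum(cls == "lying"), feeding = sum(cls == "eat"))
    }
    records <- if (n_seconds) validate_records(do.call(rbind, recs)) else
      behavior_records(as.Date(character()), character(), integer(),
                       integer(), integer(), integer())
    list(frames = frames, records = records, fps = fps, config = config)
  })
}
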