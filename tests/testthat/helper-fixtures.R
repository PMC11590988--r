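# shared fixtures, all generated in code

flat_image <- function(h, w, value = 120) caprimon::new_raster(h, w, value)

noisy_image <- function(h, w, seed = 1, base = 120, sd = 25) {
  set.seed(seed)
  caprimon:::clamp8(round(array(rnorm(h * w * 3, base, sd), dim = c(h, w, 3))))
}

random_box_table <- function(n, w = 100, h = 100, seed = 1, conf = FALSE) {
  set.seed(seed)
  x1 <- runif(n, 0, w - 2); y1 <- runif(n, 0, h - 2)
  x2 <- x1 + runif(n, 1, w - x1); y2 <- y1 + runif(n, 1, h - y1)
  caprimon::boxes(x1, y1, pmin(x2, w), pmin(y2, h),
                  sample(caprimon::behavior_classes(), n, replace = TRUE),
                  conf = if (conf) runif(n) else NULL)
}

small_scene <- function(seed = 1, n_goats = 3, size = c(240, 180), ...) {
  caprimon::generate_pen_image(
    caprimon::pen_scene_config(size, n_goats = n_goats, seed = seed, ...))
}

# integer-corner boxes on a g x g grid (0-based, half-open), as a matrix
all_grid_intervals <- function(g) {
  out <- list()
  for (a in 0:(g - 1)) for (b in (a + 1):g) out[[length(out) + 1]] <- c(a, b)
  do.call(rbind, out)
}

# independent pixel-enumeration IoU for one pair of integer boxes
enum_iou_2d <- function(p, t, g) {
  inter <- 0; ap <- 0; at <- 0
  for (x in 0:(g - 1)) for (y in 0:(g - 1)) {
    inp <- x >= p[1] && x < p[3] && y >= p[2] && y < p[4]
    int <- x >= t[1] && x < t[3] && y >= t[2] && y < t[4]
    ap <- ap + inp; at <- at + int; inter <- inter + (inp && int)
  }
  un <- ap + at - inter
  if (un == 0) 0 else inter / un
}
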