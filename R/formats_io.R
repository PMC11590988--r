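#' Read a Pascal VOC annotation file
#'
#' Parses a VOC XML file into image metadata plus a box table. VOC files use
#' 1-based inclusive integer corners; internally boxes are 0-based half-open,
#' so `xmin/ymin` are shifted down by one on read and back on write. Class
#' names are normalized to the four-class vocabulary (see
#' [behavior_classes()]).
#'
#' @param path path to a VOC XML file.
#' @return A list with `width`, `height`, `depth`, `filename`, and `boxes`
#'   (a box data frame).
#' @export
read_voc_xml <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed VOC XML in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  num <- function(node, xp) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    as.numeric(v)
  }
  w <- num(doc, ".//size/width"); h <- num(doc, ".//size/height")
  depth <- num(doc, ".//size/depth")
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0) {
    stop("VOC file '", path, "' has no valid <size> element", call. = FALSE)
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs)) {
    b <- data.frame(
      x1 = vapply(objs, num, 0, xp = ".//bndbox/xmin") - 1,
      y1 = vapply(objs, num, 0, xp = ".//bndbox/ymin") - 1,
      x2 = vapply(objs, num, 0, xp = ".//bndbox/xmax"),
      y2 = vapply(objs, num, 0, xp = ".//bndbox/ymax"),
      cls = vapply(objs, function(o)
        xml2::xml_text(xml2::xml_find_first(o, ".//name")), ""),
      conf = NA_real_, stringsAsFactors = FALSE)
    b <- validate_boxes(b, width = w, height = h)
  } else {
    b <- empty_boxes()
  }
  fn <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  list(width = w, height = h, depth = if (is.finite(depth)) depth else 3,
       filename = if (is.na(fn)) basename(path) else fn, boxes = b)
}

#' Write a Pascal VOC annotation file
#'
#' Inverse of [read_voc_xml()]. Internal float corners are written as the
#' nearest VOC integers (1-based inclusive), so a read/write round trip is
#' exact for integer coordinates and within 0.5 px otherwise.
#'
#' @param ann an [annotated_image()], or a list with `width`, `height` and
#'   `boxes` as returned by [read_voc_xml()].
#' @param path output file path.
#' @param filename value for the `<filename>` element.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(ann, path, filename = NULL) {
  if (inherits(ann, "annotated_image")) {
    meta <- list(width = ann$width, height = ann$height, depth = 3,
                 filename = if (is.null(filename)) ann$source_id else filename,
                 boxes = ann$boxes)
  } else {
    meta <- ann
    if (!is.null(filename)) meta$filename <- filename
    if (is.null(meta$filename)) meta$filename <- basename(path)
    if (is.null(meta$depth)) meta$depth <- 3
  }
  validate_boxes(meta$boxes, width = meta$width, height = meta$height)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", as.character(meta$filename))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", format(as.integer(meta$width)))
  xml2::xml_add_child(size, "height", format(as.integer(meta$height)))
  xml2::xml_add_child(size, "depth", format(as.integer(meta$depth)))
  b <- meta$boxes
  for (i in seq_len(nrow(b))) {
    obj <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(obj, "name", b$cls[i])
    xml2::xml_add_child(obj, "difficult", "0")
    bb <- xml2::xml_add_child(obj, "bndbox")
    xml2::xml_add_child(bb, "xmin", format(as.integer(round(b$x1[i])) + 1L))
    xml2::xml_add_child(bb, "ymin", format(as.integer(round(b$y1[i])) + 1L))
    xml2::xml_add_child(bb, "xmax", format(as.integer(round(b$x2[i]))))
    xml2::xml_add_child(bb, "ymax", format(as.integer(round(b$y2[i]))))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Convert between corner boxes and YOLO label lines
#'
#' YOLO labels are text lines `class_index cx cy w h` with center/size
#' normalized to `[0, 1]`. `direction = "to_yolo"` converts a box table;
#' `"from_yolo"` inverts it. Composition of the two is the identity up to
#' float formatting (6 decimals).
#'
#' @param x a box data frame (`to_yolo`) or character vector of label lines
#'   (`from_yolo`).
#' @param image_size `c(W, H)` in pixels.
#' @param direction `"to_yolo"` or `"from_yolo"`.
#' @return Character label lines, or a box data frame.
#' @export
#' @examples
#' yolo_txt_convert(boxes(10, 20, 30, 60, "eat"), c(100, 200), "to_yolo")
yolo_txt_convert <- function(x, image_size, direction = c("to_yolo", "from_yolo")) {
  direction <- match.arg(direction)
  w <- image_size[1]; h <- image_size[2]
  stopifnot(w > 0, h > 0)
  if (direction == "to_yolo") {
    b <- validate_boxes(x, width = w, height = h)
    if (!nrow(b)) return(character())
    cx <- (b$x1 + b$x2) / 2 / w; cy <- (b$y1 + b$y2) / 2 / h
    bw <- (b$x2 - b$x1) / w; bh <- (b$y2 - b$y1) / h
    vals <- cbind(cx, cy, bw, bh)
    if (any(vals < -1e-9 | vals > 1 + 1e-9)) {
      stop("normalized YOLO values fall outside [0, 1]", call. = FALSE)
    }
    sprintf("%d %.6g %.6g %.6g %.6g", class_index(b$cls), cx, cy, bw, bh)
  } else {
    lines <- trimws(as.character(x))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(empty_boxes())
    parts <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
    if (ncol(parts) != 5) stop("YOLO lines must have 5 fields", call. = FALSE)
    vals <- parts[, 2:5, drop = FALSE]
    if (any(!is.finite(vals)) || any(vals < -1e-9 | vals > 1 + 1e-9)) {
      stop("normalized YOLO values fall outside [0, 1]", call. = FALSE)
    }
    ki <- as.integer(parts[, 1])
    if (any(ki < 0 | ki > 3)) stop("class index outside 0..3", call. = FALSE)
    cx <- parts[, 2] * w; cy <- parts[, 3] * h
    bw <- parts[, 4] * w; bh <- parts[, 5] * h
    boxes(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2,
          behavior_classes()[ki + 1L])
  }
}

.record_cols <- c("date", "time", "standing", "drinking", "lying_down", "feeding")
.record_header <- c("Date", "Time", "Standing", "Drinking", "LyingDown", "Feeding")

#' Behavior record streams
#'
#' A behavior record holds per-second counts of goats in each behavior state,
#' one row per elapsed second, with the fixed column order Date, Time,
#' Standing, Drinking, LyingDown, Feeding.
#'
#' @param date `Date` (or ISO string) per row.
#' @param time `"HH:MM:SS"` second stamp per row.
#' @param standing,drinking,lying_down,feeding non-negative integer counts.
#' @return `behavior_records()`: a classed data frame of records.
#' @export
behavior_records <- function(date, time, standing, drinking, lying_down, feeding) {
  r <- data.frame(date = as.Date(date), time = as.character(time),
                  standing = as.integer(standing),
                  drinking = as.integer(drinking),
                  lying_down = as.integer(lying_down),
                  feeding = as.integer(feeding), stringsAsFactors = FALSE)
  validate_records(r)
}

#' @rdname behavior_records
#' @param r a record data frame.
#' @export
validate_records <- function(r) {
  stopifnot(is.data.frame(r))
  if (!all(.record_cols %in% names(r))) {
    stop("records need columns ", paste(.record_cols, collapse = ", "),
         call. = FALSE)
  }
  r <- r[, .record_cols]
  cnt <- as.matrix(r[, 3:6])
  if (nrow(r) && (any(is.na(cnt)) || any(cnt < 0))) {
    stop("behavior counts must be non-negative", call. = FALSE)
  }
  if (nrow(r) > 1) {
    tt <- as.POSIXct(paste(r$date, r$time), tz = "UTC")
    if (any(diff(as.numeric(tt)) < 0)) {
      stop("record stream must be non-decreasing in time", call. = FALSE)
    }
  }
  class(r) <- c("behavior_records", "data.frame")
  r
}

#' @rdname behavior_records
#' @param path CSV file path.
#' @export
write_record_csv <- function(r, path) {
  r <- validate_records(r)
  out <- data.frame(Date = format(r$date, "%Y-%m-%d"), Time = r$time,
                    Standing = r$standing, Drinking = r$drinking,
                    LyingDown = r$lying_down, Feeding = r$feeding)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname behavior_records
#' @export
read_record_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(d), .record_header)) {
    stop("record CSV header must be ", paste(.record_header, collapse = ","),
         call. = FALSE)
  }
  if (!nrow(d)) {
    return(behavior_records(as.Date(character()), character(), integer(),
                            integer(), integer(), integer()))
  }
  behavior_records(d$Date, d$Time, d$Standing, d$Drinking, d$LyingDown,
                   d$Feeding)
}

#' Iterate over frames of an image sequence
#'
#' A frame stream abstracts a video as an ordered frame source: a directory
#' of numbered PNG frames, a list of rasters, or a single `H x W x 3 x N`
#' array. Every `sample_interval`-th frame (starting at index 0) is yielded
#' with a timestamp `index / fps` in seconds.
#'
#' @param source directory path, list of rasters, or 4-d array.
#' @param sample_interval sampling stride in frames (`>= 1`).
#' @param fps nominal frames per second used to derive timestamps.
#' @return A stream object; `x$next_frame()` returns
#'   `list(frame, timestamp, index)` or `NULL` when exhausted; `x$n_frames`
#'   is the number of frames it will yield.
#' @export
frame_stream <- function(source, sample_interval = 1, fps = 30) {
  stopifnot(sample_interval >= 1, fps >= 1)
  sample_interval <- as.integer(sample_interval)
  if (is.character(source)) {
    if (!dir.exists(source)) stop("unreadable frame source: ", source,
                                  call. = FALSE)
    files <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
    get <- function(i) read_image(files[i])
    n_total <- length(files)
  } else if (is.list(source)) {
    get <- function(i) source[[i]]
    n_total <- length(source)
  } else if (is.array(source) && length(dim(source)) == 4) {
    get <- function(i) source[, , , i]
    n_total <- dim(source)[4]
  } else {
    stop("unsupported frame source", call. = FALSE)
  }
  idx <- seq(0L, length.out = max(0L, n_total %/% sample_interval),
             by = sample_interval)
  pos <- 0L
  env <- new.env()
  env$n_frames <- length(idx)
  env$fps <- fps
  env$next_frame <- function() {
    if (pos >= length(idx)) return(NULL)
    pos <<- pos + 1L
    i <- idx[pos]
    list(frame = get(i + 1L), timestamp = i / fps, index = i)
  }
  env$reset <- function() pos <<- 0L
  class(env) <- "frame_stream"
  env
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frame(s) at %g fps\n", x$n_frames, x$fps))
  invisible(x)
}
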