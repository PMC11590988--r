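#' Monitoring mode configuration
#'
#' The online system offers three operation modes, each backed by one
#' detector variant: `fast` (SNCA), `balanced` (GNCA) and `precise` (GSCA).
#' Records are written at one set of counts per second.
#'
#' @param mode `"fast"`, `"balanced"` or `"precise"`.
#' @param protocol an [eval_protocol()].
#' @param record_hz records per second (fixed at 1 by the record schema).
#' @return A `mode_config` list with the mapped `variant`.
#' @export
mode_config <- function(mode = c("fast", "balanced", "precise"),
                        protocol = eval_protocol(), record_hz = 1) {
  mode <- match.arg(mode)
  variant <- switch(mode, fast = "snca", balanced = "gnca", precise = "gsca")
  structure(list(mode = mode, variant = variant, protocol = protocol,
                 record_hz = record_hz), class = "mode_config")
}

#' Extract keyframes from a frame stream
#'
#' Samples every `floor(interval_s * fps)`-th frame starting at index 0 —
#' the sampling used to thin continuous pen video down to analysis frames.
#'
#' @param stream a [frame_stream()] (built with `sample_interval = 1`), or
#'   any list of frames.
#' @param interval_s sampling interval in seconds.
#' @param fps stream frame rate; `interval_s * fps >= 1`.
#' @return A list of `list(frame, timestamp, index)` entries.
#' @export
keyframe_extract <- function(stream, interval_s = 1, fps = 30) {
  step <- floor(interval_s * fps)
  if (step < 1) stop("interval_s * fps must be at least 1", call. = FALSE)
  if (is.list(stream) && !inherits(stream, "frame_stream")) {
    stream <- frame_stream(stream, sample_interval = 1, fps = fps)
  }
  out <- list()
  i <- 0L
  repeat {
    fr <- stream$next_frame()
    if (is.null(fr)) break
    if (fr$index %% step == 0L) out[[length(out) + 1L]] <- fr
    i <- i + 1L
  }
  out
}

#' Per-second behavior counts from detections
#'
#' Turns the post-NMS detections of one representative frame into a single
#' behavior record row: counts of goats per class at that second. Counts
#' always sum to the number of detections.
#'
#' @param detections box data frame for the frame.
#' @param timestamp `POSIXct` second stamp.
#' @return A one-row [behavior_records()] table.
#' @export
per_second_counts <- function(detections, timestamp) {
  cls <- detections$cls
  behavior_records(as.Date(timestamp, tz = "UTC"),
                   format(timestamp, "%H:%M:%S", tz = "UTC"),
                   standing = sum(cls == "stand"),
                   drinking = sum(cls == "drink"),
                   lying_down = sum(cls == "lying"),
                   feeding = sum(cls == "eat"))
}

#' Run the online monitoring pipeline
#'
#' Consumes a frame source, detects goats on one representative frame per
#' second (the first frame of that second), and emits one behavior record
#' per elapsed second, optionally persisting the stream as CSV. Runs
#' prompt-free; the per-behavior time budget is returned at the end.
#'
#' @param source a [frame_stream()], a list of frames/[annotated_image()]s,
#'   or the result of [generate_video()].
#' @param mode a [mode_config()].
#' @param detector either a `goat_detector` for the mode's variant, or a
#'   function `frame -> box data frame` (e.g. a ground-truth oracle for
#'   pipeline validation).
#' @param duration seconds to monitor; `NULL` runs until the source is
#'   exhausted. If the source runs out earlier, the stream is truncated
#'   with a warning.
#' @param fps frame rate of the source.
#' @param start_time `POSIXct` stamp of the first second.
#' @param out_csv optional path; when given, the record stream is written
#'   with [write_record_csv()].
#' @param input_size network input side when `detector` is a
#'   `goat_detector`.
#' @return A list with `records` ([behavior_records()]) and `budget`
#'   ([aggregate_time_budget()] of the stream).
#' @export
run_monitor <- function(source, mode = mode_config(), detector,
                        duration = NULL, fps = NULL,
                        start_time = as.POSIXct("2023-10-08 09:15:03",
                                                tz = "UTC"),
                        out_csv = NULL, input_size = 640) {
  if (is.list(source) && !is.null(source$frames)) {  # generate_video() result
    if (is.null(fps)) fps <- source$fps
    source <- source$frames
  }
  if (inherits(source, "frame_stream")) {
    if (is.null(fps)) fps <- source$fps
    stream <- source
  } else {
    if (is.null(fps)) fps <- 1
    px <- lapply(source, function(f)
      if (inherits(f, "annotated_image")) f$pixels else f)
    stream <- frame_stream(px, sample_interval = 1, fps = fps)
  }
  detect <- if (is.function(detector)) detector else {
    function(frame) predict(detector, frame, protocol = mode$protocol,
                            input_size = input_size)
  }
  rows <- list()
  want <- if (is.null(duration)) Inf else duration
  sec_seen <- -1L
  truncated <- FALSE
  repeat {
    if (length(rows) >= want) break
    fr <- stream$next_frame()
    if (is.null(fr)) {
      truncated <- is.finite(want) && length(rows) < want
      break
    }
    sec <- as.integer(floor(fr$timestamp))
    if (sec == sec_seen) next  # one representative frame per second
    sec_seen <- sec
    det <- detect(fr$frame)
    rows[[length(rows) + 1L]] <-
      per_second_counts(det, start_time + sec)
  }
  if (truncated) {
    warning("frame source exhausted after ", length(rows), " of ", want,
            " seconds; record stream truncated")
  }
  records <- if (length(rows)) validate_records(do.call(rbind, rows)) else
    behavior_records(as.Date(character()), character(), integer(), integer(),
                     integer(), integer())
  if (!is.null(out_csv)) write_record_csv(records, out_csv)
  list(records = records, budget = aggregate_time_budget(records))
}

#' Behavior time budgets
#'
#' Accumulated goat-time per behavior over a record stream:
#' `sum(count) * period_s` goat-seconds for each of the four behaviors.
#' Budgets are additive over stream concatenation and scale linearly with
#' the record period.
#'
#' @param records a [behavior_records()] table.
#' @param period_s seconds represented by each record row.
#' @return Named numeric vector (class `time_budget`) with components
#'   `standing`, `drinking`, `lying_down`, `feeding`, in goat-seconds.
#' @export
aggregate_time_budget <- function(records, period_s = 1) {
  r <- validate_records(records)
  structure(c(standing = sum(r$standing), drinking = sum(r$drinking),
              lying_down = sum(r$lying_down),
              feeding = sum(r$feeding)) * period_s,
            class = "time_budget")
}

#' Compare system and manual time budgets
#'
#' Per-behavior relative difference `100 * (system - manual) / manual` (%),
#' plus the pooled feeding+standing difference — the reconciliation check
#' used when trough visits are hard to score: a goat with its head in the
#' trough may be logged as feeding by the system but standing by an
#' observer, so the pooled total is the fairer comparison.
#'
#' @param system,manual `time_budget` vectors (or named numerics).
#' @return A list with `per_behavior` (named %, `NA` where the manual value
#'   is 0) and `pooled_feeding_standing` (%).
#' @export
compare_budgets <- function(system, manual) {
  nm <- c("standing", "drinking", "lying_down", "feeding")
  s <- as.numeric(system[nm]); m <- as.numeric(manual[nm])
  per <- ifelse(m > 0, 100 * (s - m) / m, NA_real_)
  names(per) <- nm
  if (any(is.na(per))) {
    warning("manual budget is 0 for: ",
            paste(nm[is.na(per)], collapse = ", "),
            "; relative difference undefined there")
  }
  pool_m <- m[1] + m[4]
  pooled <- if (pool_m > 0) 100 * ((s[1] + s[4]) - pool_m) / pool_m else
    NA_real_
  list(per_behavior = per, pooled_feeding_standing = pooled)
}

#' VOC-style mean average precision
#'
#' Per-class precision-recall evaluation by greedy matching at IoU >= 0.5:
#' detections are sorted by descending confidence, each matching at most
#' one unmatched truth (the highest-IoU one); AP is the area under the
#' interpolated PR curve sampled at 101 recall points, and mAP the mean
#' over classes present in the ground truth (absent classes are excluded
#' with a warning).
#'
#' @param detections list of box data frames with `conf` (one per image).
#' @param ground_truth list of box data frames (same length/order).
#' @param protocol an [eval_protocol()]; detections below
#'   `conf_threshold` are ignored and the match threshold is
#'   `iou_threshold`.
#' @param iou_threshold match threshold (default 0.5).
#' @return A list with `per_class_ap` (named vector) and `map`.
#' @export
evaluate_map <- function(detections, ground_truth, protocol = eval_protocol(),
                         iou_threshold = 0.5) {
  stopifnot(length(detections) == length(ground_truth))
  classes <- behavior_classes()
  gt_count <- vapply(classes, function(cl)
    sum(vapply(ground_truth, function(g) sum(g$cls == cl), 0)), 0)
  aps <- rep(NA_real_, length(classes))
  names(aps) <- classes
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    if (gt_count[ci] == 0) next
    recs <- list()
    for (im in seq_along(detections)) {
      d <- detections[[im]]
      d <- d[d$cls == cl & !is.na(d$conf) &
               d$conf >= protocol$conf_threshold, , drop = FALSE]
      if (nrow(d)) {
        recs[[length(recs) + 1L]] <- data.frame(im = im, conf = d$conf,
                                                x1 = d$x1, y1 = d$y1,
                                                x2 = d$x2, y2 = d$y2)
      }
    }
    if (!length(recs)) { aps[ci] <- 0; next }
    dd <- do.call(rbind, recs)
    dd <- dd[order(-dd$conf), , drop = FALSE]
    matched <- lapply(ground_truth, function(g) rep(FALSE, nrow(g)))
    tp <- numeric(nrow(dd)); fp <- numeric(nrow(dd))
    for (k in seq_len(nrow(dd))) {
      im <- dd$im[k]
      g <- ground_truth[[im]]
      gi <- which(g$cls == cl)
      if (length(gi)) {
        ious <- box_iou_matrix(dd[k, , drop = FALSE], g[gi, , drop = FALSE])
        best <- which.max(ious[1, ])
        if (ious[1, best] >= iou_threshold && !matched[[im]][gi[best]]) {
          matched[[im]][gi[best]] <- TRUE
          tp[k] <- 1
        } else fp[k] <- 1
      } else fp[k] <- 1
    }
    ctp <- cumsum(tp); cfp <- cumsum(fp)
    recall <- ctp / gt_count[ci]
    precision <- ctp / pmax(ctp + cfp, 1e-12)
    # 101-point interpolation: max precision at recall >= r
    ap <- 0
    for (r in seq(0, 1, by = 0.01)) {
      p <- precision[recall >= r - 1e-12]
      ap <- ap + (if (length(p)) max(p) else 0)
    }
    aps[ci] <- ap / 101
  }
  if (any(is.na(aps))) {
    warning("no ground truth for: ",
            paste(classes[is.na(aps)], collapse = ", "),
            "; excluded from the mean")
  }
  list(per_class_ap = aps, map = mean(aps, na.rm = TRUE))
}
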