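test_that("VOC files round-trip through read and write", {
  tmp <- withr::local_tempdir()
  # empty annotation
  f0 <- file.path(tmp, "empty.xml")
  write_voc_xml(list(width = 320, height = 240, boxes = boxes()), f0)
  r0 <- read_voc_xml(f0)
  expect_equal(r0$width, 320)
  expect_equal(r0$height, 240)
  expect_equal(nrow(r0$boxes), 0)
  # single object with known integer corners
  f1 <- file.path(tmp, "one.xml")
  write_voc_xml(list(width = 100, height = 100,
                     boxes = boxes(10, 20, 30, 60, "eat")), f1)
  r1 <- read_voc_xml(f1)
  expect_equal(unlist(r1$boxes[1, 1:4]), c(x1 = 10, y1 = 20, x2 = 30, y2 = 60))
  expect_equal(r1$boxes$cls, "eat")
  # boundary box spanning the whole image survives
  f2 <- file.path(tmp, "full.xml")
  write_voc_xml(list(width = 64, height = 48,
                     boxes = boxes(0, 0, 64, 48, "stand")), f2)
  r2 <- read_voc_xml(f2)
  expect_equal(unlist(r2$boxes[1, 1:4]), c(x1 = 0, y1 = 0, x2 = 64, y2 = 48))
  # random float fixtures: round trip within the 0.5 px rounding rule,
  # and a second write/read cycle is bit-stable
  for (s in 1:20) {
    b <- random_box_table(5, 200, 150, seed = s)
    fp <- file.path(tmp, sprintf("rt%d.xml", s))
    write_voc_xml(list(width = 200, height = 150, boxes = b), fp)
    got <- read_voc_xml(fp)$boxes
    expect_equal(got$cls, b$cls)
    expect_lt(max(abs(as.matrix(got[, 1:4]) - as.matrix(b[, 1:4]))), 0.5 + 1e-9)
    write_voc_xml(list(width = 200, height = 150, boxes = got), fp)
    expect_identical(read_voc_xml(fp)$boxes, got)
  }
})

test_that("VOC reading rejects bad input", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.xml")
  writeLines("<annotation><size>", bad)
  expect_error(read_voc_xml(bad), "malformed")
  unk <- file.path(tmp, "unk.xml")
  writeLines(paste0("<annotation><size><width>10</width><height>10</height>",
                    "<depth>3</depth></size><object><name>horse</name>",
                    "<bndbox><xmin>1</xmin><ymin>1</ymin><xmax>5</xmax>",
                    "<ymax>5</ymax></bndbox></object></annotation>"), unk)
  expect_error(read_voc_xml(unk), "lying, stand, drink, eat")
  expect_error(write_voc_xml(list(width = 10, height = 10,
                                  boxes = boxes(0, 0, 20, 5, "eat")),
                             file.path(tmp, "oob.xml")),
               "beyond the image")
})

test_that("YOLO conversion matches hand arithmetic and inverts exactly", {
  # full-frame box
  expect_equal(yolo_txt_convert(boxes(0, 0, 100, 200, "stand"),
                                c(100, 200), "to_yolo"),
               "1 0.5 0.5 1 1")
  # hand-computed example: cx = (10+30)/2/100 = 0.2, etc.
  line <- yolo_txt_convert(boxes(10, 20, 30, 60, "eat"), c(100, 200), "to_yolo")
  vals <- as.numeric(strsplit(line, " ")[[1]])
  expect_equal(vals, c(3, 0.2, 0.2, 0.2, 0.2))
  # composition is the identity on 100 random boxes
  b <- random_box_table(100, 640, 360, seed = 9)
  back <- yolo_txt_convert(yolo_txt_convert(b, c(640, 360), "to_yolo"),
                           c(640, 360), "from_yolo")
  expect_equal(as.matrix(back[, 1:4]), as.matrix(b[, 1:4]), tolerance = 1e-4)
  expect_equal(back$cls, b$cls)
  expect_error(yolo_txt_convert("0 0.5 0.5 1.5 1", c(10, 10), "from_yolo"),
               "outside")
})

test_that("behavior record CSV preserves the fixed schema", {
  tmp <- withr::local_tempdir()
  # the record-sheet style row: 8 standing, 1 drinking, 10 lying, 3 feeding
  r <- behavior_records("2023-10-08", "09:15:03", 8, 1, 10, 3)
  f <- file.path(tmp, "rec.csv")
  write_record_csv(r, f)
  txt <- readLines(f)
  expect_equal(txt[1], "Date,Time,Standing,Drinking,LyingDown,Feeding")
  expect_equal(txt[2], "2023-10-08,09:15:03,8,1,10,3")
  expect_equal(read_record_csv(f), r)
  # empty stream -> header-only file
  e <- behavior_records(as.Date(character()), character(), integer(),
                        integer(), integer(), integer())
  write_record_csv(e, f)
  expect_equal(length(readLines(f)), 1)
  expect_equal(nrow(read_record_csv(f)), 0)
  # 100 random records round-trip exactly
  set.seed(4)
  n <- 100
  r2 <- behavior_records(as.Date("2023-10-08") + (0:(n - 1)) %/% 86400,
                         sprintf("%02d:%02d:%02d", (0:(n - 1)) %/% 3600,
                                 ((0:(n - 1)) %/% 60) %% 60, (0:(n - 1)) %% 60),
                         sample(0:20, n, TRUE), sample(0:20, n, TRUE),
                         sample(0:20, n, TRUE), sample(0:20, n, TRUE))
  write_record_csv(r2, f)
  expect_equal(read_record_csv(f), r2)
  expect_error(behavior_records("2023-10-08", "00:00:00", -1, 0, 0, 0),
               "non-negative")
})

test_that("frame streams sample with the declared offset convention", {
  frames <- lapply(1:300, function(i) flat_image(8, 8, i %% 255))
  fs <- frame_stream(frames, sample_interval = 30, fps = 30)
  expect_equal(fs$n_frames, 10)
  got <- list(); repeat { f <- fs$next_frame(); if (is.null(f)) break
    got[[length(got) + 1]] <- f }
  expect_equal(vapply(got, function(x) x$index, 0L), seq(0, 270, by = 30))
  ts <- vapply(got, function(x) x$timestamp, 0)
  expect_true(all(diff(ts) > 0))
  # interval 1 yields every frame in order
  fs1 <- frame_stream(frames[1:7], sample_interval = 1, fps = 30)
  expect_equal(fs1$n_frames, 7)
  # floor(N / interval) frames, first at index 0
  fs2 <- frame_stream(frames[1:10], sample_interval = 3, fps = 30)
  expect_equal(fs2$n_frames, 3)
  expect_error(frame_stream("/no/such/dir"), "unreadable")
})

test_that("frame streams read PNG directories", {
  tmp <- withr::local_tempdir()
  for (i in 1:4) {
    write_image(flat_image(6, 6, 40 * i), file.path(tmp, sprintf("f%03d.png", i)))
  }
  fs <- frame_stream(tmp, sample_interval = 2, fps = 2)
  expect_equal(fs$n_frames, 2)
  f1 <- fs$next_frame()
  expect_equal(dim(f1$frame), c(6, 6, 3))
  expect_equal(f1$frame[1, 1, 1], 40)
})
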