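test_that("mot_csv rows are converted to corner form and row order preserved", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,id,x,y,w,h,conf,class",
               "5,1,10,20,30,40,1.0,dolphin",
               "5,2,0,0,10,10,0.8,dolphin"), p)
  set <- read_detections(p)
  expect_equal(nrow(set$detections), 2)
  expect_equal(unlist(set$detections[1, c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE),
               c(10, 20, 40, 60))
  expect_equal(set$detections$id, c("1", "2")) # order within frame preserved
  expect_true(all(set$detections$source == "model"))
})

test_that("header-only file yields an empty set; conf -1 marks ground truth", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,id,x,y,w,h,conf,class", p)
  expect_equal(nrow(read_detections(p)$detections), 0)

  writeLines(c("frame,id,x,y,w,h,conf,class", "0,a7,1,2,3,4,-1,dolphin"), p)
  set <- read_detections(p)
  expect_equal(set$detections$source, "ground_truth")
  expect_equal(set$detections$id, "a7")
  expect_true(is.na(set$detections$confidence))
})

test_that("malformed rows raise parse errors naming the line", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,id,x,y,w,h,conf,class", "1,1,2,3,4,5,0.5"), p)
  expect_error(read_detections(p), "line 2", class = "droneval_parse_error")

  writeLines(c("frame,id,x,y,w,h,conf,class", "1,1,2,3,oops,5,0.5,dolphin"), p)
  expect_error(read_detections(p), "line 2", class = "droneval_parse_error")

  writeLines(c("frame,id,x,y,w,h,conf,class", "1,1,2,3,-4,5,0.5,dolphin"), p)
  expect_error(read_detections(p), "w and h", class = "droneval_validation_error")

  expect_error(read_detections(file.path(tempdir(), "nope.csv")),
               class = "droneval_io_error")
})

test_that("write/read round trip is the identity (50 random detections)", {
  withr::local_seed(7)
  set <- random_set(50, frames = 0:30)
  p <- withr::local_tempfile(fileext = ".csv")
  write_detections(set, p)
  back <- read_detections(p, flight_id = set$flight_id,
                          treatment = set$treatment,
                          frame_range = set$frame_range,
                          frame_width = set$frame_width,
                          frame_height = set$frame_height)
  expect_identical(back$detections$frame, set$detections$frame)
  expect_identical(back$detections$source, set$detections$source)
  for (col in c("x_min", "y_min", "x_max", "y_max", "confidence")) {
    expect_lt(max(abs(back$detections[[col]] - set$detections[[col]])), 1e-9)
  }
  # empty set -> header-only file
  empty <- detection_set(flight_id = "fx", frame_range = c(0, 0))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_detections(empty, p2)
  expect_equal(length(readLines(p2)), 1)
})

test_that("clip_to_frame_range keeps exactly the in-range detections", {
  det <- data.frame(frame = c(1L, 5L, 9L), id = NA, x_min = 0, y_min = 0,
                    x_max = 10, y_max = 10, confidence = 0.9,
                    class = "dolphin", source = "model")
  set <- detection_set(det, frame_range = c(0, 20))
  clipped <- clip_to_frame_range(set, c(4, 9))
  expect_equal(clipped$detections$frame, c(5L, 9L))
  expect_equal(clipped$frame_range, c(4L, 9L))
  # full-cover range is the identity on the detections
  expect_equal(clip_to_frame_range(set, c(0, 20))$detections, set$detections)
  # disjoint range -> empty set, not an error
  expect_equal(nrow(clip_to_frame_range(set, c(50, 60))$detections), 0)

  # brute-force count oracle on random frames
  withr::local_seed(11)
  big <- random_set(100, frames = 0:99)
  expect_equal(nrow(clip_to_frame_range(big, c(25, 74))$detections),
               sum(big$detections$frame >= 25 & big$detections$frame <= 74))
})

test_that("central_region_filter keeps boxes whose centre is central", {
  mk <- function(x1, y1, x2, y2) {
    detection_set(data.frame(frame = 0L, id = NA, x_min = x1, y_min = y1,
                             x_max = x2, y_max = y2, confidence = 0.9,
                             class = "dolphin", source = "model"),
                  frame_range = c(0, 0), frame_width = 1000, frame_height = 800)
  }
  expect_equal(nrow(central_region_filter(mk(490, 390, 510, 410), 0.1)$detections), 1)
  expect_equal(nrow(central_region_filter(mk(0, 0, 4, 4), 0.8)$detections), 0)

  # brute-force centre-test oracle on 200 random boxes
  withr::local_seed(3)
  set <- random_set(200, frames = 0:9)
  kept <- central_region_filter(set, 0.8)
  d <- set$detections
  cx <- (d$x_min + d$x_max) / 2; cy <- (d$y_min + d$y_max) / 2
  oracle <- sum(abs(cx - 500) <= 0.8 * 1000 / 2 & abs(cy - 400) <= 0.8 * 800 / 2)
  expect_equal(nrow(kept$detections), oracle)
})

test_that("clip and central filter are idempotent, commute, and do not mutate input", {
  withr::local_seed(21)
  set <- random_set(120, frames = 0:49)
  snapshot <- unserialize(serialize(set, NULL))
  r <- c(10, 35)
  a <- central_region_filter(clip_to_frame_range(set, r), 0.7)
  b <- clip_to_frame_range(central_region_filter(set, 0.7), r)
  expect_equal(a$detections, b$detections)
  expect_equal(clip_to_frame_range(a, r)$detections, a$detections)
  expect_equal(central_region_filter(a, 0.7)$detections, a$detections)
  expect_identical(set, snapshot) # value semantics
})

test_that("interpolate_track fills gaps linearly and holds the last box", {
  tr <- gt_track("a", data.frame(frame = c(0L, 10L), x_min = c(0, 10),
                                 y_min = 0, x_max = c(10, 20), y_max = 10))
  out <- interpolate_track(tr, max_extension = 0)
  b <- track_boxes(out)
  mid <- b[b$frame == 5, ]
  expect_equal(unlist(mid[c("x_min", "y_min", "x_max", "y_max")],
                      use.names = FALSE), c(5, 0, 15, 10))
  expect_equal(interpolated_frames(out), setdiff(0:10, c(0L, 10L)))

  # single keyframe, extension 3 -> three held copies
  tr1 <- gt_track("b", data.frame(frame = 4L, x_min = 1, y_min = 2,
                                  x_max = 3, y_max = 4))
  out1 <- interpolate_track(tr1, max_extension = 3)
  expect_equal(interpolated_frames(out1), 5:7)
  expect_true(all(track_boxes(out1)$x_max == 3))

  # per-coordinate convex-combination oracle at frames 0 and 4
  withr::local_seed(5)
  A <- random_boxes(1); B <- random_boxes(1)
  tr2 <- gt_track("c", data.frame(frame = c(0L, 4L), rbind(A, B)))
  got <- track_boxes(interpolate_track(tr2, 0))
  f1 <- got[got$frame == 1, c("x_min", "y_min", "x_max", "y_max")]
  expect_equal(unlist(f1, use.names = FALSE),
               as.numeric(0.75 * A + 0.25 * B), tolerance = 1e-12)

  expect_error(gt_track("z", data.frame(frame = integer(0), x_min = numeric(0),
                                        y_min = numeric(0), x_max = numeric(0),
                                        y_max = numeric(0))),
               class = "droneval_validation_error")
})

test_that("interpolated boxes always satisfy the box invariants", {
  withr::local_seed(13)
  for (k in 1:25) {
    A <- random_boxes(1); B <- random_boxes(1)
    tr <- gt_track("p", data.frame(frame = c(0L, sample(2:30, 1)), rbind(A, B)))
    b <- track_boxes(interpolate_track(tr, 10))
    expect_true(all(b$x_min < b$x_max & b$y_min < b$y_max))
  }
})

test_that("tracks_to_detection_set emits one detection per (track, frame)", {
  mk <- function(id, frames) {
    gt_track(id, data.frame(frame = frames, x_min = 0, y_min = 0,
                            x_max = 10, y_max = 10))
  }
  set <- tracks_to_detection_set(list(mk("a", 0:9), mk("b", 0:9)),
                                 frame_range = c(0, 9))
  expect_equal(nrow(set$detections), 20)
  expect_equal(nrow(tracks_to_detection_set(list(), frame_range = c(0, 0))$detections), 0)

  # overlapping coverage: per-frame gt count equals tracks covering the frame
  set2 <- tracks_to_detection_set(list(mk("a", 0:5), mk("b", 3:8)),
                                  frame_range = c(0, 8))
  per_frame <- table(set2$detections$frame)
  oracle <- vapply(0:8, function(f) sum(f %in% 0:5, f %in% 3:8), 0)
  expect_equal(as.numeric(per_frame[as.character(0:8)]), oracle)

  expect_error(tracks_to_detection_set(list(mk("a", 0:5), mk("a", 2:4))),
               "duplicate", class = "droneval_validation_error")
})

test_that("track keyframe CSV round-trips", {
  withr::local_seed(31)
  tracks <- list(gt_track("a1", data.frame(frame = c(0L, 8L), rbind(random_boxes(1), random_boxes(1)))),
                 gt_track("a2", data.frame(frame = c(2L, 5L), rbind(random_boxes(1), random_boxes(1)))))
  p <- withr::local_tempfile(fileext = ".csv")
  write_track_keyframes(tracks, p)
  back <- read_track_keyframes(p)
  expect_setequal(names(back), c("a1", "a2"))
  expect_equal(back$a1$keyframes, tracks[[1]]$keyframes, tolerance = 1e-9)
})
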