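test_that("iou handles identity, disjoint and partial overlap", {
  expect_equal(iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  # hand arithmetic: intersection 50, union 150
  expect_equal(iou(c(0, 0, 10, 10), c(0, 5, 10, 15)), 1 / 3)
})

test_that("iou is symmetric and scale invariant", {
  withr::local_seed(41)
  for (k in 1:40) {
    a <- random_boxes(1); b <- random_boxes(1)
    expect_equal(iou(a, b), iou(b, a))
    s <- runif(1, 0.1, 10)
    expect_equal(iou(a * s, b * s), iou(a, b), tolerance = 1e-12)
    expect_equal(iou(a, b), oracle_iou(as.numeric(a), as.numeric(b)),
                 tolerance = 1e-12)
  }
})

test_that("match_frame classifies the elementary cases in both fp modes", {
  box <- c(0, 0, 10, 10)
  r <- match_frame(box, box)
  expect_equal(c(r$tp, r$fp, r$fn), c(1, 0, 0))

  # model box with no ground truth at all is FP in both modes
  for (mode in c("no_overlap", "strict")) {
    r <- match_frame(NULL, box, match_config(fp_mode = mode))
    expect_equal(c(r$tp, r$fp, r$fn), c(0, 1, 0))
  }

  # sub-threshold overlap (iou 1/3 < 0.5): literal mode discards, strict counts FP
  lit <- match_frame(box, c(0, 5, 10, 15), match_config(fp_mode = "no_overlap"))
  expect_equal(c(lit$tp, lit$fp, lit$fn), c(0, 0, 1))
  expect_equal(lit$discarded_model, 1L)
  strict <- match_frame(box, c(0, 5, 10, 15), match_config(fp_mode = "strict"))
  expect_equal(c(strict$tp, strict$fp, strict$fn), c(0, 1, 1))
})

test_that("optimal assignment equals the exhaustive oracle on random 4x4 frames", {
  withr::local_seed(43)
  for (k in 1:30) {
    gt <- random_boxes(4, W = 120, H = 120, min_size = 20, max_size = 60)
    md <- random_boxes(4, W = 120, H = 120, min_size = 20, max_size = 60)
    for (thr in c(0.3, 0.5)) {
      got <- match_frame(gt, md, match_config(thr, assignment = "optimal"))
      oracle <- oracle_best_assignment(gt, md, thr)
      expect_equal(got$tp, oracle$card)
      expect_equal(sum(got$pairs$iou), oracle$total, tolerance = 1e-9)
    }
  }
})

test_that("greedy TP never exceeds optimal TP; both conserve gt boxes", {
  withr::local_seed(47)
  for (k in 1:60) {
    n <- sample(0:5, 1); m <- sample(0:5, 1)
    gt <- random_boxes(max(n, 1), W = 150, H = 150, min_size = 25, max_size = 70)[seq_len(n), , drop = FALSE]
    md <- random_boxes(max(m, 1), W = 150, H = 150, min_size = 25, max_size = 70)[seq_len(m), , drop = FALSE]
    g <- match_frame(gt, md, match_config(0.4, assignment = "greedy"))
    o <- match_frame(gt, md, match_config(0.4, assignment = "optimal"))
    expect_lte(g$tp, o$tp)
    expect_equal(g$tp + g$fn, n)
    expect_equal(o$tp + o$fn, n)
    # strict mode: tp + fp covers every model box
    s <- match_frame(gt, md, match_config(0.4, fp_mode = "strict"))
    expect_equal(s$tp + s$fp, m)
    # literal mode never counts more FPs than strict
    expect_lte(g$fp, s$fp)
  }
})

test_that("raising the IoU threshold never increases TP", {
  withr::local_seed(53)
  for (k in 1:20) {
    gt <- random_boxes(4, W = 200, H = 200, min_size = 30, max_size = 80)
    md <- random_boxes(4, W = 200, H = 200, min_size = 30, max_size = 80)
    tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                  function(t) match_frame(gt, md, match_config(t))$tp, 0L)
    expect_true(all(diff(tps) <= 0))
  }
})

test_that("greedy ties break deterministically by gt then model index", {
  gt <- rbind(c(0, 0, 10, 10), c(20, 0, 30, 10))
  md <- rbind(c(20, 0, 30, 10), c(0, 0, 10, 10)) # both ious are exactly 1
  r <- match_frame(gt, md)
  expect_equal(r$pairs$gt, c(1L, 2L))
  expect_equal(r$pairs$model, c(2L, 1L))
})

test_that("match_sequence sums per-frame results over the common range", {
  withr::local_seed(59)
  gt <- random_set(60, frames = 0:19, source = "ground_truth")
  md <- random_set(55, frames = 0:19, source = "model")
  cfg <- match_config(0.3)
  counts <- match_sequence(gt, md, cfg)
  # frame-by-frame brute-force summation oracle via match_frame
  tp <- fp <- fn <- 0
  for (f in 0:19) {
    g <- gt$detections[gt$detections$frame == f, ]
    m <- md$detections[md$detections$frame == f, ]
    r <- match_frame(g, m, cfg)
    tp <- tp + r$tp; fp <- fp + r$fp; fn <- fn + r$fn
  }
  expect_equal(c(counts$tp, counts$fp, counts$fn), c(tp, fp, fn))
  expect_equal(length(counts$matched_ious), counts$tp)
  expect_equal(counts$tp + counts$fn, nrow(gt$detections))
})

test_that("identical streams give perfect counts; empty model gives all FN", {
  withr::local_seed(61)
  gt <- random_set(40, frames = 0:9, source = "ground_truth")
  perfect <- perfect_model_copy(gt)
  counts <- match_sequence(gt, perfect)
  expect_equal(c(counts$tp, counts$fp, counts$fn), c(40, 0, 0))
  expect_true(all(counts$matched_ious == 1))

  empty <- detection_set(frame_range = gt$frame_range,
                         frame_width = gt$frame_width,
                         frame_height = gt$frame_height)
  counts0 <- match_sequence(gt, empty)
  expect_equal(c(counts0$tp, counts0$fp, counts0$fn), c(0, 0, 40))

  mismatched <- detection_set(frame_range = c(0, 5),
                              frame_width = gt$frame_width,
                              frame_height = gt$frame_height)
  expect_error(match_sequence(gt, mismatched), "clip",
               class = "droneval_validation_error")
})

test_that("match details CSV lists every TP/FP/FN/DISCARDED event", {
  withr::local_seed(67)
  gt <- random_set(20, frames = 0:4, source = "ground_truth")
  md <- random_set(25, frames = 0:4, source = "model")
  counts <- match_sequence(gt, md, match_config(0.3), keep_frames = TRUE)
  p <- withr::local_tempfile(fileext = ".csv")
  write_match_details(counts, p)
  dump <- utils::read.csv(p)
  expect_equal(sum(dump$kind == "TP"), counts$tp)
  expect_equal(sum(dump$kind == "FP"), counts$fp)
  expect_equal(sum(dump$kind == "FN"), counts$fn)
})
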