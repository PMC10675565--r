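# Fixture builders and independent oracles. The oracles deliberately avoid
# the package's own code paths: plain arithmetic, enumeration, brute force.

random_boxes <- function(n, W = 1000, H = 800, min_size = 5, max_size = 80) {
  w <- runif(n, min_size, max_size)
  h <- runif(n, min_size, max_size)
  x <- runif(n, 0, W - w)
  y <- runif(n, 0, H - h)
  cbind(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
}

random_set <- function(n, frames = 0:19, source = "model",
                       W = 1000, H = 800, frame_range = range(frames)) {
  b <- random_boxes(n, W, H)
  det <- data.frame(frame = sample(frames, n, replace = TRUE),
                    id = if (source == "ground_truth") paste0("a", seq_len(n)) else NA_character_,
                    b,
                    confidence = if (source == "model") runif(n) else NA_real_,
                    class = "dolphin", source = source,
                    stringsAsFactors = FALSE)
  detection_set(det, flight_id = "fx", treatment = "RGB",
                frame_range = frame_range, frame_width = W, frame_height = H)
}

# independent IoU for the oracles (straight-line area arithmetic)
oracle_iou <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(iw, 0) * max(ih, 0)
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  inter / (area(a) + area(b) - inter)
}

# Exhaustive one-to-one assignment oracle: enumerate every injective mapping
# of ground-truth boxes to model boxes over threshold-passing pairs and
# return the best (cardinality, then total IoU). Exponential; fine for <= 4x4.
oracle_best_assignment <- function(gt, model, thr) {
  n <- nrow(gt); m <- nrow(model)
  ious <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ious[i, j] <- oracle_iou(gt[i, ], model[j, ])
  }
  best <- list(card = 0L, total = 0)
  recurse <- function(i, used, card, total) {
    if (i > n) {
      if (card > best$card || (card == best$card && total > best$total)) {
        best <<- list(card = card, total = total)
      }
      return(invisible())
    }
    recurse(i + 1L, used, card, total)
    for (j in seq_len(m)) {
      if (!used[j] && ious[i, j] >= thr) {
        used[j] <- TRUE
        recurse(i + 1L, used, card + 1L, total + ious[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(m), 0L, 0)
  best
}

# a noise-free "model" stream that copies the ground truth exactly
perfect_model_copy <- function(gt_set) {
  det <- gt_set$detections
  det$source <- "model"
  det$confidence <- 1
  det$id <- NA_character_
  detection_set(det, gt_set$flight_id, gt_set$treatment, gt_set$frame_range,
                gt_set$frame_width, gt_set$frame_height)
}

# two-animal flight with perfect detection and no noise of any kind
noise_free_config <- function(n_frames = 300, seed = 5) {
  animals <- list(
    animal_model("a", speed = 2, surface_duration = 60, dive_duration = 120,
                 max_depth = 5, start_x = 1200, start_y = 900),
    animal_model("b", speed = 1.5, surface_duration = 80, dive_duration = 100,
                 max_depth = 4, start_x = 2500, start_y = 1400, phase0 = 40))
  simulation_config(n_frames = n_frames, animals = animals,
                    detectability = test_detectability(d50 = 1000, jitter_sd = 0,
                                                       fp_rate = 0),
                    offsets = c(RGB = 0L, GREEN = 0L, GREEN_POL = 0L),
                    seed = seed, merge_prob = 0)
}

# small deterministic detectability for simulator tests
test_detectability <- function(d50 = 4, jitter_sd = 0, fp_rate = 0,
                               light_fraction = 1, slope = 0.5) {
  out <- lapply(droneval:::TREATMENTS, function(tr) {
    treatment_detectability(tr, d50 = d50, slope = slope,
                            jitter_sd = jitter_sd, fp_rate = fp_rate,
                            light_fraction = light_fraction)
  })
  names(out) <- droneval:::TREATMENTS
  out
}
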