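# Synthetic flight generator. Stands in for the study's raw footage: dolphins
# surface and dive on a piecewise-sinusoidal depth cycle while drifting
# horizontally; each camera treatment detects a surfaced animal with a
# depth-dependent logistic probability scaled by how much light its filter
# passes; detected boxes get Gaussian corner jitter; clutter adds Poisson
# false positives; closely overlapping detected animals are occasionally
# merged into a single box, which is what produces the secondary low-IoU
# mode seen with tightly grouped dolphins.

#' Describe one simulated animal
#'
#' @param animal_id identity label.
#' @param speed horizontal speed, pixels/frame.
#' @param surface_duration,dive_duration dive-cycle phase lengths in frames
#'   (depth is 0 at the surface and follows half a sine up to `max_depth`
#'   during a dive, so it is continuous and 0 at every surfacing).
#' @param max_depth deepest point of a dive, metres.
#' @param body_w,body_h box size at the surface, pixels.
#' @param start_x,start_y initial box-centre position, pixels.
#' @param heading initial heading, radians (0 = rightward).
#' @param phase0 frames into the dive cycle at frame 0 (0 = just surfaced).
#' @return an object of class `animal_model`.
#' @export
animal_model <- function(animal_id, speed = 2, surface_duration = 90,
                         dive_duration = 300, max_depth = 8,
                         body_w = 60, body_h = 25,
                         start_x = 1920, start_y = 1080,
                         heading = 0, phase0 = 0) {
  if (surface_duration <= 0 || dive_duration <= 0) {
    stop_validation("surface_duration and dive_duration must be > 0")
  }
  if (max_depth < 0) stop_validation("max_depth must be >= 0")
  structure(list(animal_id = as.character(animal_id), speed = speed,
                 surface_duration = as.integer(surface_duration),
                 dive_duration = as.integer(dive_duration),
                 max_depth = max_depth, body_w = body_w, body_h = body_h,
                 start_x = start_x, start_y = start_y,
                 heading = heading, phase0 = as.integer(phase0)),
            class = "animal_model")
}

#' Treatment-specific detectability parameters
#'
#' Detection probability at depth `d` is
#' `plogis((d50 - d) / slope) * light_fraction^gamma`: a logistic
#' availability curve (50% at `d50`, sharper for smaller `slope`) scaled by
#' a light penalty for the filtered sensors (a polariser passes roughly half
#' the light of the plain bandpass filter, hence a lower `light_fraction`).
#'
#' @param treatment treatment code.
#' @param d50 depth of 50% detection probability, metres.
#' @param slope logistic scale, metres.
#' @param jitter_sd sd of the Gaussian corner-localisation noise, pixels.
#' @param fp_rate expected clutter false positives per frame.
#' @param light_fraction relative light reaching the sensor, in `(0, 1]`.
#' @return an object of class `treatment_detectability`.
#' @export
treatment_detectability <- function(treatment, d50, slope = 0.5,
                                    jitter_sd = 3, fp_rate = 0.01,
                                    light_fraction = 1) {
  if (d50 <= 0 || slope <= 0) stop_validation("d50 and slope must be > 0")
  if (light_fraction <= 0 || light_fraction > 1) {
    stop_validation("light_fraction must be in (0, 1]")
  }
  structure(list(treatment = match_treatment(treatment), d50 = d50,
                 slope = slope, jitter_sd = jitter_sd, fp_rate = fp_rate,
                 light_fraction = light_fraction),
            class = "treatment_detectability")
}

detection_probability <- function(depth, det, gamma = 0.5) {
  stats::plogis((det$d50 - depth) / det$slope) * det$light_fraction^gamma
}

#' Full simulation configuration
#'
#' @param n_frames number of frames to simulate.
#' @param animals list of [animal_model()] objects (at least one).
#' @param detectability named list of [treatment_detectability()] objects,
#'   one per treatment. The default preset must satisfy
#'   `d50(RGB) >= d50(GREEN) >= d50(GREEN_POL)`.
#' @param offsets named integer vector of planted camera frame offsets.
#' @param seed master RNG seed; per-treatment noise streams use sub-seeds
#'   derived from it by fixed offsets, so treatments are conditionally
#'   independent given the shared truth.
#' @param frame_width,frame_height,fps acquisition defaults (4k UHD, 30 fps).
#' @param gamma exponent of the light penalty `light_fraction^gamma`.
#' @param annotation_margin metres beyond the most sensitive treatment's
#'   `d50` up to which the annotator still boxes the animal.
#' @param max_extension frames the annotator holds the last box after the
#'   animal disappears (see [interpolate_track()]).
#' @param merge_prob probability that a pair of detected, truly overlapping
#'   boxes is merged into one union box in a given frame.
#' @param heading_noise_sd sd of the per-frame heading perturbation, radians.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_frames, animals, detectability,
                              offsets = c(RGB = 0L, GREEN = 0L, GREEN_POL = 0L),
                              seed = 42, frame_width = 3840, frame_height = 2160,
                              fps = 30, gamma = 0.5, annotation_margin = 1,
                              max_extension = 60, merge_prob = 0.35,
                              heading_noise_sd = 0.02) {
  if (length(animals) == 0) stop_validation("need at least one animal")
  if (!all(vapply(animals, inherits, TRUE, "animal_model"))) {
    stop_validation("animals must be animal_model objects")
  }
  if (!all(TREATMENTS %in% names(detectability))) {
    stop_validation("detectability needs entries for ",
                    paste(TREATMENTS, collapse = ", "))
  }
  offsets <- offsets[TREATMENTS]
  if (anyNA(offsets)) stop_validation("offsets need entries for all treatments")
  structure(list(n_frames = as.integer(n_frames), animals = animals,
                 detectability = detectability,
                 offsets = vapply(offsets, as.integer, 0L),
                 seed = as.integer(seed),
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 fps = fps, gamma = gamma,
                 annotation_margin = annotation_margin,
                 max_extension = as.integer(max_extension),
                 merge_prob = merge_prob,
                 heading_noise_sd = heading_noise_sd),
            class = "simulation_config")
}

# Depth at integer frame f for one animal: 0 while surfaced, half-sine dive.
animal_depth <- function(animal, frames) {
  cycle <- animal$surface_duration + animal$dive_duration
  phase <- (frames + animal$phase0) %% cycle
  diving <- phase >= animal$surface_duration
  d <- numeric(length(frames))
  d[diving] <- animal$max_depth *
    sin(pi * (phase[diving] - animal$surface_duration) / animal$dive_duration)
  d
}

# cutoff below which the annotator can still see the animal: deep enough that
# even the most sensitive sensor has essentially lost it
annotation_cutoff <- function(config) {
  max(vapply(config$detectability, function(d) d$d50, 0)) + config$annotation_margin
}

#' Simulate ground-truth animal tracks
#'
#' Deterministic given the config seed. Each animal follows its dive cycle,
#' drifts with small heading noise, and reflects off the frame borders. A
#' ground-truth keyframe is laid down on every frame where the animal is
#' shallower than the annotation cutoff (the most sensitive treatment's
#' `d50` plus `annotation_margin`); deeper stretches become gaps, to be
#' filled by [interpolate_track()] exactly as manual annotation would.
#'
#' @param config a [simulation_config()].
#' @return list with `tracks` (list of [gt_track], keyframes on sightable
#'   frames only) and `truth` (data.frame `frame`, `id`, box corners,
#'   `depth` for every animal on every frame).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  frames <- seq_len(config$n_frames) - 1L
  cutoff <- annotation_cutoff(config)
  W <- config$frame_width; H <- config$frame_height
  truth <- vector("list", length(config$animals))
  tracks <- vector("list", length(config$animals))
  for (a in seq_along(config$animals)) {
    an <- config$animals[[a]]
    hw <- an$body_w / 2; hh <- an$body_h / 2
    depth <- animal_depth(an, frames)
    x <- numeric(config$n_frames); y <- numeric(config$n_frames)
    x[1] <- min(max(an$start_x, hw), W - hw)
    y[1] <- min(max(an$start_y, hh), H - hh)
    heading <- an$heading
    noise <- stats::rnorm(config$n_frames, 0, config$heading_noise_sd)
    for (f in seq_len(config$n_frames - 1L)) {
      heading <- heading + noise[f]
      nx <- x[f] + an$speed * cos(heading)
      ny <- y[f] + an$speed * sin(heading)
      if (nx < hw)      { nx <- 2 * hw - nx;           heading <- pi - heading }
      if (nx > W - hw)  { nx <- 2 * (W - hw) - nx;     heading <- pi - heading }
      if (ny < hh)      { ny <- 2 * hh - ny;           heading <- -heading }
      if (ny > H - hh)  { ny <- 2 * (H - hh) - ny;     heading <- -heading }
      x[f + 1L] <- min(max(nx, hw), W - hw)
      y[f + 1L] <- min(max(ny, hh), H - hh)
    }
    truth[[a]] <- data.frame(frame = frames, id = an$animal_id,
                             x_min = x - hw, y_min = y - hh,
                             x_max = x + hw, y_max = y + hh,
                             depth = depth, stringsAsFactors = FALSE)
    vis <- depth < cutoff
    if (!any(vis)) {
      stop_validation("animal ", an$animal_id,
                      " is never sightable; lower max_depth or raise the cutoff")
    }
    kf <- truth[[a]][vis, c("frame", BOX_COLS)]
    tracks[[a]] <- gt_track(an$animal_id, kf)
  }
  list(tracks = tracks, truth = do.call(rbind, truth))
}

# clamp a jittered box into the frame, preserving validity
sanitise_boxes <- function(b, W, H, min_size = 1) {
  x1 <- pmin(b[, 1], b[, 3]); x2 <- pmax(b[, 1], b[, 3])
  y1 <- pmin(b[, 2], b[, 4]); y2 <- pmax(b[, 2], b[, 4])
  x1 <- pmin(pmax(x1, 0), W - min_size); x2 <- pmax(pmin(x2, W), x1 + min_size)
  y1 <- pmin(pmax(y1, 0), H - min_size); y2 <- pmax(pmin(y2, H), y1 + min_size)
  cbind(x_min = x1, y_min = y1, x_max = x2, y_max = y2)
}

#' Simulate one treatment's model-detection stream
#'
#' Each true box is detected independently with probability
#' `plogis((d50 - depth)/slope) * light_fraction^gamma`; detected boxes get
#' independent Gaussian jitter on each corner (clamped back into the frame);
#' per frame, `Poisson(fp_rate)` clutter boxes are added at uniform positions
#' with sizes drawn from the animal size distribution; confidences are
#' uniform on `[0.5, 1]`. Detected boxes of truly overlapping animals are
#' merged into one union box with probability `merge_prob`.
#'
#' The detection and jitter draws are laid out so that, for a fixed seed,
#' raising `d50` only ever adds detections (common random numbers), which is
#' what makes recall monotone in `d50`.
#'
#' @param truth per-frame truth table from [simulate_tracks()].
#' @param det a [treatment_detectability()].
#' @param config the [simulation_config()].
#' @param seed RNG seed for this stream (a sub-seed in [simulate_flight()]).
#' @return a model [detection_set]; attribute `"events"` holds a data.frame
#'   (`frame`, `id`, `depth`, `detected`) of the per-box Bernoulli outcomes,
#'   used for detectability-curve fitting.
#' @export
simulate_detections <- function(truth, det, config, seed = config$seed) {
  stopifnot(inherits(det, "treatment_detectability"),
            inherits(config, "simulation_config"))
  set.seed(seed)
  n <- nrow(truth)
  W <- config$frame_width; H <- config$frame_height
  u_detect <- stats::runif(n)
  jitter <- matrix(stats::rnorm(4L * n, 0, det$jitter_sd), ncol = 4)
  conf <- stats::runif(n, 0.5, 1)
  p <- detection_probability(truth$depth, det, config$gamma)
  detected <- u_detect < p

  boxes <- as.matrix(truth[BOX_COLS]) + jitter
  boxes <- sanitise_boxes(boxes, W, H)
  n_det <- sum(detected)
  model <- data.frame(frame = truth$frame[detected],
                      id = rep(NA_character_, n_det),
                      boxes[detected, , drop = FALSE],
                      confidence = conf[detected],
                      class = rep("dolphin", n_det),
                      source = rep("model", n_det), stringsAsFactors = FALSE)

  # clutter false positives (positions uniform over the full frame, so the
  # central-region filter has something to remove)
  n_fp <- stats::rpois(config$n_frames, det$fp_rate)
  tot_fp <- sum(n_fp)
  if (tot_fp > 0) {
    mean_w <- mean(vapply(config$animals, function(a) a$body_w, 0))
    mean_h <- mean(vapply(config$animals, function(a) a$body_h, 0))
    fw <- pmax(abs(stats::rnorm(tot_fp, mean_w, 0.2 * mean_w)), 5)
    fh <- pmax(abs(stats::rnorm(tot_fp, mean_h, 0.2 * mean_h)), 5)
    fw <- pmin(fw, W - 1); fh <- pmin(fh, H - 1)
    fx <- stats::runif(tot_fp, 0, W - fw)
    fy <- stats::runif(tot_fp, 0, H - fh)
    clutter <- data.frame(frame = rep(seq_len(config$n_frames) - 1L, n_fp),
                          id = NA_character_,
                          x_min = fx, y_min = fy, x_max = fx + fw, y_max = fy + fh,
                          confidence = stats::runif(tot_fp, 0.5, 1),
                          class = "dolphin", source = "model",
                          stringsAsFactors = FALSE)
    model <- rbind(model, clutter)
  }

  # merge detected boxes of truly overlapping animals (grouped dolphins are
  # sometimes boxed as one by the detector)
  if (config$merge_prob > 0 && any(detected)) {
    tr_idx <- which(detected)
    by_frame <- split(tr_idx, truth$frame[detected])
    by_frame <- by_frame[lengths(by_frame) >= 2]
    drop_keys <- character(0)
    merged_rows <- list()
    for (idx in by_frame) {
      tb <- as.matrix(truth[idx, BOX_COLS])
      M <- iou_matrix(tb, tb)
      used <- logical(length(idx))
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (i < j && !used[i] && !used[j] && M[i, j] > 0 &&
            stats::runif(1) < config$merge_prob) {
          used[i] <- used[j] <- TRUE
          bi <- boxes[idx[i], ]; bj <- boxes[idx[j], ]
          merged_rows[[length(merged_rows) + 1L]] <- data.frame(
            frame = truth$frame[idx[i]], id = NA_character_,
            x_min = min(bi[1], bj[1]), y_min = min(bi[2], bj[2]),
            x_max = max(bi[3], bj[3]), y_max = max(bi[4], bj[4]),
            confidence = max(conf[idx[i]], conf[idx[j]]),
            class = "dolphin", source = "model", stringsAsFactors = FALSE)
          drop_keys <- c(drop_keys,
                         paste(truth$frame[idx[c(i, j)]], truth$id[idx[c(i, j)]]))
        }
      }
    }
    if (length(merged_rows)) {
      # rows of `model` are the detected truth rows (in truth order) followed
      # by clutter, so key them the same way to drop the merged originals
      det_keys <- c(paste(truth$frame[detected], truth$id[detected]),
                    rep("", nrow(model) - sum(detected)))
      model <- model[!(det_keys %in% drop_keys), , drop = FALSE]
      model <- rbind(model, do.call(rbind, merged_rows))
    }
  }

  model <- model[order(model$frame), , drop = FALSE]
  rownames(model) <- NULL
  set <- detection_set(model, flight_id = "sim", treatment = det$treatment,
                       frame_range = c(0L, config$n_frames - 1L),
                       frame_width = W, frame_height = H)
  attr(set, "events") <- data.frame(frame = truth$frame, id = truth$id,
                                    depth = truth$depth, detected = detected,
                                    stringsAsFactors = FALSE)
  set
}

#' Fit a logistic detectability curve to simulated detection events
#'
#' Maximum-likelihood logistic regression of the per-box detection indicator
#' on depth, reparameterised to `(d50, slope)`:
#' `p(d) = plogis((d50 - d)/slope)`. Only meaningful when
#' `light_fraction = 1` (no multiplicative ceiling below 1).
#'
#' @param events data.frame with `depth` and `detected` columns (the
#'   `"events"` attribute of [simulate_detections()]).
#' @return list with `d50` and `slope` estimates.
#' @export
fit_detectability <- function(events) {
  if (length(unique(events$detected)) < 2) {
    stop_validation("need both detected and missed events to fit a curve")
  }
  fit <- stats::glm(detected ~ depth, family = stats::binomial(), data = events)
  b <- stats::coef(fit)
  list(d50 = unname(-b[1] / b[2]), slope = unname(-1 / b[2]))
}

#' Simulate a complete multi-camera flight
#'
#' One shared ground truth; three model streams that differ only in their
#' treatment detectability and in independent noise (sub-seeds derived from
#' the master seed by fixed offsets). The planted camera offsets are added
#' to each treatment's frame indices — each camera records on its own
#' clock — and every surfacing moment is exported as an event anchor so the
#' synchronisation stage can recover the offsets.
#'
#' @param config a [simulation_config()].
#' @param max_anchors cap on exported surfacing events.
#' @return list: `gt` (ground-truth [detection_set], interpolated and
#'   flattened), `model` (named list of model [detection_set]s on their
#'   camera clocks), `anchors` (event-anchor data.frame), `tracks`, `truth`,
#'   `config`.
#' @export
simulate_flight <- function(config, max_anchors = 8) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_tracks(config)
  range <- c(0L, config$n_frames - 1L)
  interp <- lapply(sim$tracks, interpolate_track, max_extension = config$max_extension)
  gt <- tracks_to_detection_set(interp, flight_id = "sim", treatment = "RGB",
                                frame_range = NULL,
                                frame_width = config$frame_width,
                                frame_height = config$frame_height)
  gt <- clip_to_frame_range(gt, range)

  # surfacing moments: depth returns to 0 after a dive
  surfacings <- do.call(rbind, lapply(split(sim$truth, sim$truth$id), function(d) {
    d <- d[order(d$frame), ]
    up <- which(d$depth == 0 & c(FALSE, d$depth[-nrow(d)] > 0))
    if (length(up)) data.frame(id = d$id[1], frame = d$frame[up]) else NULL
  }))
  anchors <- NULL
  if (!is.null(surfacings) && nrow(surfacings)) {
    surfacings <- surfacings[order(surfacings$frame), , drop = FALSE]
    surfacings <- utils::head(surfacings, max_anchors)
    anchors <- do.call(rbind, lapply(seq_len(nrow(surfacings)), function(i) {
      data.frame(event_id = sprintf("surface_%02d", i),
                 camera = TREATMENTS,
                 frame = surfacings$frame[i] + unname(config$offsets[TREATMENTS]),
                 stringsAsFactors = FALSE)
    }))
  }

  sub_seeds <- config$seed + c(RGB = 101L, GREEN = 202L, GREEN_POL = 303L)
  model <- lapply(TREATMENTS, function(tr) {
    s <- simulate_detections(sim$truth, config$detectability[[tr]], config,
                             seed = sub_seeds[[tr]])
    s$flight_id <- "sim"
    # shift onto this camera's clock (apply_offset subtracts, so negate)
    apply_offset(s, -config$offsets[[tr]])
  })
  names(model) <- TREATMENTS
  list(gt = gt, model = model, anchors = anchors,
       tracks = sim$tracks, truth = sim$truth, config = config)
}

#' Calibrate box-corner jitter against a target IoU statistic
#'
#' Monte-Carlo root-finding: for a fixed box size, find the corner-jitter sd
#' such that a statistic of the IoU between the true and the jittered box
#' equals `target`. The IoU distribution under corner jitter is left-skewed
#' (bounded above by 1), so its mode sits above its mean; the observation
#' being emulated is where the distribution *peaks*, hence the default
#' statistic is the mode (kernel-density peak of the Monte-Carlo draws).
#' Common random numbers across candidate sd values keep the objective
#' smooth for the root finder.
#'
#' @param box_w,box_h box size in pixels.
#' @param target target value of the statistic.
#' @param n_draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @param statistic `"mode"` (default) or `"mean"`.
#' @return the calibrated jitter sd (pixels).
#' @export
calibrate_jitter_sd <- function(box_w = 60, box_h = 25, target = 0.74,
                                n_draws = 10000, seed = 1,
                                statistic = c("mode", "mean")) {
  statistic <- match.arg(statistic)
  set.seed(seed)
  Z <- matrix(stats::rnorm(4L * n_draws), ncol = 4)
  iou_draws <- function(s) {
    x1 <- Z[, 1] * s; y1 <- Z[, 2] * s
    x2 <- box_w + Z[, 3] * s; y2 <- box_h + Z[, 4] * s
    ix <- pmin(x2, box_w) - pmax(x1, 0)
    iy <- pmin(y2, box_h) - pmax(y1, 0)
    inter <- pmax(ix, 0) * pmax(iy, 0)
    union <- box_w * box_h + pmax(x2 - x1, 0) * pmax(y2 - y1, 0) - inter
    inter / union
  }
  stat <- switch(statistic,
                 mean = function(v) mean(v),
                 mode = function(v) {
                   d <- stats::density(v, bw = 0.02, from = 0, to = 1, n = 512)
                   d$x[which.max(d$y)]
                 })
  stats::uniroot(function(s) stat(iou_draws(s)) - target,
                 interval = c(0.01, min(box_w, box_h) / 2))$root
}
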