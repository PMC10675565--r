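# Ground-truth tracks: per-animal keyframed box sequences. Annotators box an
# animal on the frames where it is sightable; gaps (dives) are filled by
# linear interpolation and the last box is held briefly after the animal
# disappears, mirroring manual annotation practice.

#' Construct a ground-truth track
#'
#' Annotated keyframes and interpolation-produced boxes are kept separate:
#' `keyframes` holds what the annotator drew, `interpolated` what
#' [interpolate_track()] filled in, and their frame indices are disjoint by
#' construction.
#'
#' @param animal_id character identity label.
#' @param keyframes data.frame with columns `frame`, `x_min`, `y_min`,
#'   `x_max`, `y_max`; frame indices must be strictly increasing.
#' @param interpolated data.frame with the same columns for frames whose box
#'   was produced by interpolation rather than annotation; frame indices
#'   must be disjoint from the keyframe indices.
#' @return an object of class `gt_track`.
#' @export
gt_track <- function(animal_id, keyframes, interpolated = NULL) {
  need <- c("frame", BOX_COLS)
  tidy <- function(df, what) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (!all(need %in% names(df))) {
      stop_validation(what, " need columns ", paste(need, collapse = ", "))
    }
    df <- df[need]
    df$frame <- as.integer(df$frame)
    df <- df[order(df$frame), , drop = FALSE]
    rownames(df) <- NULL
    if (nrow(df) && is.unsorted(df$frame, strictly = TRUE)) {
      stop_validation(what, " frame indices must be strictly increasing")
    }
    if (nrow(df)) validate_boxes(df, what = what)
    df
  }
  kf <- tidy(keyframes, "keyframes")
  if (nrow(kf) == 0) stop_validation("a track needs at least one keyframe")
  interp <- if (is.null(interpolated)) kf[0, ] else tidy(interpolated, "interpolated boxes")
  if (length(intersect(interp$frame, kf$frame))) {
    stop_validation("interpolated frames must be disjoint from keyframe indices")
  }
  structure(list(animal_id = as.character(animal_id), keyframes = kf,
                 interpolated = interp),
            class = "gt_track")
}

#' Frames of a track whose box was interpolated
#'
#' @param track a [gt_track].
#' @return sorted integer vector of frame indices.
#' @export
interpolated_frames <- function(track) {
  stopifnot(inherits(track, "gt_track"))
  track$interpolated$frame
}

#' All boxes of a track, annotated and interpolated
#'
#' @param track a [gt_track].
#' @return data.frame `frame`, box corners, `interpolated` flag, ordered by
#'   frame.
#' @export
track_boxes <- function(track) {
  stopifnot(inherits(track, "gt_track"))
  kf <- track$keyframes; kf[["interpolated"]] <- rep(FALSE, nrow(kf))
  ip <- track$interpolated; ip[["interpolated"]] <- rep(TRUE, nrow(ip))
  out <- rbind(kf, ip)
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.gt_track <- function(x, ...) {
  b <- track_boxes(x)
  cat(sprintf("<gt_track> animal %s: %d keyframes + %d interpolated, frames [%d, %d]\n",
              x$animal_id, nrow(x$keyframes), nrow(x$interpolated),
              min(b$frame), max(b$frame)))
  invisible(x)
}

#' Fill a track's sightability gaps by interpolation
#'
#' For every gap between consecutive keyframes, boxes on the intermediate
#' frames are produced by independent linear interpolation of each of the
#' four corner coordinates; after the final keyframe the last box is held
#' constant for up to `max_extension` frames (annotation continued "beyond
#' sightability" for a short while after an animal dived). All produced
#' frames are recorded in `interpolated_frames`.
#'
#' @param track a [gt_track].
#' @param max_extension integer; frames to hold the final box (default 60,
#'   i.e. 2 s at 30 fps).
#' @return a new [gt_track] whose `interpolated` table covers every gap
#'   frame and the held extension; the annotated keyframes are untouched.
#' @export
interpolate_track <- function(track, max_extension = 60) {
  stopifnot(inherits(track, "gt_track"))
  kf <- track$keyframes
  frames <- kf$frame
  full <- seq(frames[1], frames[length(frames)])
  gap_frames <- setdiff(full, frames)
  filled <- data.frame(frame = gap_frames)
  for (col in BOX_COLS) {
    filled[[col]] <- if (length(gap_frames) == 0) numeric(0) else
      stats::approx(frames, kf[[col]], xout = gap_frames, method = "linear")$y
  }
  if (max_extension > 0) {
    last <- kf[nrow(kf), ]
    ext <- data.frame(frame = seq(last$frame + 1, last$frame + max_extension),
                      x_min = last$x_min, y_min = last$y_min,
                      x_max = last$x_max, y_max = last$y_max)
    filled <- rbind(filled, ext)
  }
  gt_track(track$animal_id, kf, filled)
}

#' Flatten tracks into a ground-truth detection set
#'
#' Emits one ground-truth detection per (track, frame) pair. Animals sharing
#' frames each contribute their own box (every individual is tracked and
#' boxed separately); a duplicate (animal, frame) pair is a validation error.
#'
#' @param tracks list of [gt_track] objects (normally interpolated first).
#' @param flight_id,treatment,frame_range,frame_width,frame_height passed to
#'   [detection_set()].
#' @param class_label class recorded on every detection.
#' @return a [detection_set] with `source = "ground_truth"`.
#' @export
tracks_to_detection_set <- function(tracks, flight_id = "flight",
                                    treatment = "RGB", frame_range = NULL,
                                    frame_width = 3840, frame_height = 2160,
                                    class_label = "dolphin") {
  if (inherits(tracks, "gt_track")) tracks <- list(tracks)
  parts <- lapply(tracks, function(tr) {
    stopifnot(inherits(tr, "gt_track"))
    b <- track_boxes(tr)
    data.frame(frame = b$frame, id = tr$animal_id,
               x_min = b$x_min, y_min = b$y_min,
               x_max = b$x_max, y_max = b$y_max,
               confidence = NA_real_, class = class_label,
               source = "ground_truth", stringsAsFactors = FALSE)
  })
  det <- if (length(parts)) do.call(rbind, parts) else empty_detections()
  if (anyDuplicated(det[c("id", "frame")])) {
    stop_validation("duplicate (animal_id, frame) pair across tracks")
  }
  det <- det[order(det$frame, det$id), , drop = FALSE]
  rownames(det) <- NULL
  detection_set(det, flight_id, treatment, frame_range, frame_width, frame_height)
}

#' Read track keyframes from CSV
#'
#' Format: `animal_id,frame,x_min,y_min,x_max,y_max`, one row per annotated
#' keyframe.
#'
#' @param path CSV file path.
#' @return a list of [gt_track] objects, one per animal.
#' @export
read_track_keyframes <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "frame", BOX_COLS)
  if (!all(need %in% names(df))) {
    stop_parse(path, ": expected header '", paste(need, collapse = ","), "'")
  }
  lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    gt_track(d$animal_id[1], d[c("frame", BOX_COLS)])
  })
}

#' Write track keyframes to CSV
#'
#' @param tracks list of [gt_track] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_keyframes <- function(tracks, path) {
  if (inherits(tracks, "gt_track")) tracks <- list(tracks)
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    cbind(animal_id = tr$animal_id, tr$keyframes)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
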