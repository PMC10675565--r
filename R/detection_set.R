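# A detection_set is the per-flight, per-treatment container used throughout:
# a data.frame of boxes (ground truth and/or model) plus flight metadata.

DET_COLS <- c("frame", "id", "x_min", "y_min", "x_max", "y_max",
              "confidence", "class", "source")

empty_detections <- function() {
  data.frame(frame = integer(0), id = character(0),
             x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0),
             confidence = numeric(0), class = character(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Construct a detection set
#'
#' Bundles a table of per-frame bounding boxes with the flight metadata the
#' evaluation needs: treatment, inclusive frame range (0-based indices) and
#' frame dimensions in pixels. Boxes are stored in corner form with continuous
#' coordinates so interpolation never rounds.
#'
#' @param detections data.frame with columns `frame`, `id`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `confidence`, `class`, `source`; `source` is
#'   `"ground_truth"` (requires `id`, `confidence` is `NA`) or `"model"`
#'   (requires `confidence` in `[0, 1]`).
#' @param flight_id character scalar naming the flight.
#' @param treatment one of `"RGB"`, `"GREEN"`, `"GREEN_POL"` (display names
#'   `"Green"`/`"Green/Pol"` are accepted).
#' @param frame_range integer length 2, inclusive `(start, end)`; defaults to
#'   the span of the detections (or `c(0, 0)` when empty).
#' @param frame_width,frame_height frame dimensions in pixels (4k UHD default).
#' @return an object of class `detection_set`.
#' @export
detection_set <- function(detections = empty_detections(),
                          flight_id = "flight",
                          treatment = "RGB",
                          frame_range = NULL,
                          frame_width = 3840, frame_height = 2160) {
  treatment <- match_treatment(treatment)
  det <- as.data.frame(detections, stringsAsFactors = FALSE)
  missing_cols <- setdiff(DET_COLS, names(det))
  if ("frame" %in% missing_cols) stop_validation("detections need a 'frame' column")
  for (col in missing_cols) {
    det[[col]] <- switch(col,
      id = NA_character_, confidence = NA_real_,
      class = "dolphin", source = "ground_truth",
      stop_validation("detections need a '", col, "' column"))
  }
  det <- det[DET_COLS]
  det$frame <- as.integer(det$frame)
  det$id <- as.character(det$id)
  if (is.null(frame_range)) {
    frame_range <- if (nrow(det)) range(det$frame) else c(0L, 0L)
  }
  frame_range <- as.integer(frame_range)
  set <- structure(list(flight_id = flight_id, treatment = treatment,
                        frame_range = frame_range,
                        frame_width = as.integer(frame_width),
                        frame_height = as.integer(frame_height),
                        detections = det),
                   class = "detection_set")
  validate_detection_set(set)
  set
}

validate_detection_set <- function(set) {
  stopifnot(inherits(set, "detection_set"))
  fr <- set$frame_range
  det <- set$detections
  if (length(fr) != 2 || anyNA(fr) || fr[1] > fr[2] || fr[1] < 0) {
    stop_validation("frame_range must be non-negative with start <= end")
  }
  if (set$frame_width <= 0 || set$frame_height <= 0) {
    stop_validation("frame dimensions must be positive")
  }
  if (nrow(det) == 0) return(invisible(set))
  if (anyNA(det$frame) || any(det$frame < fr[1]) || any(det$frame > fr[2])) {
    stop_validation("every detection's frame index must lie inside frame_range [",
                    fr[1], ", ", fr[2], "]")
  }
  validate_boxes(det, what = "detection")
  if (any(det$x_min < 0) || any(det$y_min < 0) ||
      any(det$x_max > set$frame_width) || any(det$y_max > set$frame_height)) {
    stop_validation("boxes must lie within [0, frame_width] x [0, frame_height]")
  }
  if (!all(det$source %in% c("ground_truth", "model"))) {
    stop_validation("source must be 'ground_truth' or 'model'")
  }
  gt <- det$source == "ground_truth"
  if (any(gt & (is.na(det$id) | det$id == ""))) {
    stop_validation("ground-truth detections must carry an animal id")
  }
  conf <- det$confidence[!gt]
  if (anyNA(conf) || any(conf < 0) || any(conf > 1)) {
    stop_validation("model detections must carry a confidence in [0, 1]")
  }
  invisible(set)
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set> flight %s, treatment %s\n", x$flight_id,
              TREATMENT_LABELS[[x$treatment]]))
  cat(sprintf("  frames [%d, %d], %d x %d px, %d detections (%d ground truth, %d model)\n",
              x$frame_range[1], x$frame_range[2], x$frame_width, x$frame_height,
              nrow(x$detections), sum(x$detections$source == "ground_truth"),
              sum(x$detections$source == "model")))
  invisible(x)
}

n_detections <- function(set) nrow(set$detections)

MOT_HEADER <- c("frame", "id", "x", "y", "w", "h", "conf", "class")

#' Read a bounding-box stream
#'
#' Reads detections from the MOT-challenge-like CSV dialect
#' `frame,id,x,y,w,h,conf,class` where `(x, y)` is the top-left corner and
#' `w, h` are positive extents. Boxes are converted to corner form
#' (`x_max = x + w`). Rows with `conf == -1` are ground truth (MOT
#' convention); all others are model detections.
#'
#' @param path CSV file path.
#' @param dialect only `"mot_csv"` is supported.
#' @inheritParams detection_set
#' @return a [detection_set].
#' @export
read_detections <- function(path, dialect = "mot_csv",
                            flight_id = "flight", treatment = "RGB",
                            frame_range = NULL,
                            frame_width = 3840, frame_height = 2160) {
  if (!identical(dialect, "mot_csv")) {
    stop_validation("unsupported dialect '", dialect, "'")
  }
  if (!file.exists(path)) stop_io("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop_parse(path, ": empty file, expected a header row")
  header <- strsplit(trimws(lines[1]), ",")[[1]]
  if (!identical(tolower(trimws(header)), MOT_HEADER)) {
    stop_parse(path, ": line 1: expected header '",
               paste(MOT_HEADER, collapse = ","), "'")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(detection_set(empty_detections(), flight_id, treatment,
                         frame_range, frame_width, frame_height))
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8)) {
    i <- which(nf != 8)[1]
    stop_parse(path, ": line ", i + 1, ": expected 8 comma-separated fields, got ", nf[i])
  }
  m <- matrix(trimws(unlist(fields)), ncol = 8, byrow = TRUE)
  num <- suppressWarnings(apply(m[, c(1, 3:7), drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 6)
  if (anyNA(num)) {
    i <- which(apply(num, 1, anyNA))[1]
    stop_parse(path, ": line ", i + 1, ": non-numeric value in a numeric field")
  }
  frame <- num[, 1]; x <- num[, 2]; y <- num[, 3]
  w <- num[, 4]; h <- num[, 5]; conf <- num[, 6]
  if (any(w <= 0) || any(h <= 0)) {
    i <- which(w <= 0 | h <= 0)[1]
    stop_validation(path, ": line ", i + 1, ": w and h must be > 0")
  }
  is_gt <- conf == -1
  det <- data.frame(frame = as.integer(frame),
                    id = ifelse(m[, 2] %in% c("-1", ""), NA_character_, m[, 2]),
                    x_min = x, y_min = y, x_max = x + w, y_max = y + h,
                    confidence = ifelse(is_gt, NA_real_, conf),
                    class = m[, 8],
                    source = ifelse(is_gt, "ground_truth", "model"),
                    stringsAsFactors = FALSE)
  detection_set(det, flight_id, treatment, frame_range, frame_width, frame_height)
}

#' Write a bounding-box stream
#'
#' Inverse of [read_detections()]: emits the `mot_csv` dialect with boxes in
#' top-left + extent form. Ground-truth rows get `conf = -1`; model rows
#' without an identity get `id = -1`. `read_detections(write_detections(x))`
#' reproduces `x` exactly (coordinates to better than `1e-9`).
#'
#' @param set a [detection_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(set, path) {
  validate_detection_set(set)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("no such directory: ", dir)
  det <- set$detections
  fmt <- function(v) formatC(v, format = "g", digits = 15)
  rows <- if (nrow(det)) {
    paste(det$frame,
          ifelse(is.na(det$id), "-1", det$id),
          fmt(det$x_min), fmt(det$y_min),
          fmt(det$x_max - det$x_min), fmt(det$y_max - det$y_min),
          ifelse(det$source == "ground_truth", "-1", fmt(det$confidence)),
          det$class, sep = ",")
  } else character(0)
  ok <- tryCatch({
    writeLines(c(paste(MOT_HEADER, collapse = ","), rows), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write ", path)
  invisible(path)
}

#' Clip a detection set to a frame range
#'
#' Keeps only detections whose frame index lies in the inclusive range and
#' intersects the set's frame range with it. Used to restrict the model
#' stream to the frame sequences that carry ground truth. Disjoint ranges
#' yield an empty set, not an error.
#'
#' @param set a [detection_set].
#' @param range inclusive integer `(start, end)`.
#' @return a new [detection_set]; the input is never modified.
#' @export
clip_to_frame_range <- function(set, range) {
  validate_detection_set(set)
  range <- as.integer(range)
  if (length(range) != 2 || anyNA(range) || range[1] > range[2]) {
    stop_validation("range must be (start, end) with start <= end")
  }
  lo <- max(set$frame_range[1], range[1])
  hi <- min(set$frame_range[2], range[2])
  if (lo > hi) {
    return(detection_set(empty_detections(), set$flight_id, set$treatment,
                         c(max(0L, range[1]), max(0L, range[1])),
                         set$frame_width, set$frame_height))
  }
  keep <- set$detections$frame >= lo & set$detections$frame <= hi
  detection_set(set$detections[keep, , drop = FALSE], set$flight_id,
                set$treatment, c(lo, hi), set$frame_width, set$frame_height)
}

#' Keep detections centred in the middle of the frame
#'
#' Retains detections whose box centre falls in the centred rectangle of
#' width `central_fraction * frame_width` and height
#' `central_fraction * frame_height`. This mirrors restricting analysis to
#' the middle of the frame, away from lens vignetting and the spectral
#' filters' angular phase shift.
#'
#' @param set a [detection_set].
#' @param central_fraction fraction of each dimension kept, in `(0, 1]`.
#' @return a new [detection_set].
#' @export
central_region_filter <- function(set, central_fraction = 0.8) {
  validate_detection_set(set)
  if (!is.numeric(central_fraction) || central_fraction <= 0 || central_fraction > 1) {
    stop_validation("central_fraction must be in (0, 1]")
  }
  det <- set$detections
  cx <- (det$x_min + det$x_max) / 2
  cy <- (det$y_min + det$y_max) / 2
  hw <- set$frame_width * central_fraction / 2
  hh <- set$frame_height * central_fraction / 2
  keep <- abs(cx - set$frame_width / 2) <= hw & abs(cy - set$frame_height / 2) <= hh
  detection_set(det[keep, , drop = FALSE], set$flight_id, set$treatment,
                set$frame_range, set$frame_width, set$frame_height)
}

#' Shift a detection stream onto the common timeline
#'
#' Subtracts a camera's estimated frame offset from every frame index (and
#' from the frame range) so that streams from different cameras share one
#' timeline. `apply_offset(apply_offset(x, k), -k)` is the identity.
#'
#' @param set a [detection_set].
#' @param offset integer frame offset of this camera relative to the
#'   reference (as reported by [estimate_offsets()]).
#' @return a new [detection_set].
#' @export
apply_offset <- function(set, offset) {
  validate_detection_set(set)
  offset <- as.integer(offset)
  if (length(offset) != 1 || is.na(offset)) stop_validation("offset must be a single integer")
  if (offset == 0) return(set)
  new_range <- set$frame_range - offset
  if (new_range[1] < 0) {
    stop_validation("offset ", offset, " would produce negative frame indices")
  }
  det <- set$detections
  det$frame <- det$frame - offset
  detection_set(det, set$flight_id, set$treatment, new_range,
                set$frame_width, set$frame_height)
}
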