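# Multi-camera frame synchronisation. Short-lived events visible in all
# cameras (e.g. a dolphin breaking the surface) anchor the streams: the
# per-camera frame index of each event gives the relative frame offset, and
# residual disagreement between anchors flags a sync failure.

#' Read event anchors from CSV
#'
#' Format: `event_id,camera,frame`, one row per (event, camera) sighting.
#'
#' @param path CSV file path.
#' @return data.frame with columns `event_id`, `camera`, `frame`.
#' @export
read_event_anchors <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "camera", "frame")
  if (!all(need %in% names(df))) {
    stop_parse(path, ": expected header '", paste(need, collapse = ","), "'")
  }
  df$event_id <- as.character(df$event_id)
  df$camera <- as.character(df$camera)
  df$frame <- as.integer(df$frame)
  df[need]
}

#' Estimate per-camera frame offsets from event anchors
#'
#' For each camera, the offset relative to the reference is the median over
#' anchors of `frame_camera - frame_reference`, rounded half away from zero
#' to an integer (the acquisition is frame-locked, so sub-frame offsets are
#' not meaningful). The median is robust to a single misidentified event.
#' Per-event residuals (difference minus offset) expose anchors that
#' disagree.
#'
#' @param anchors data.frame as returned by [read_event_anchors()]; every
#'   event must include the reference camera, and each anchor needs at least
#'   two cameras.
#' @param reference camera label used as the zero of the common timeline.
#' @param tolerance integer frames; the report `passed` flag requires
#'   `max_abs_offset <= tolerance` and all residuals zero (default 1 frame,
#'   the agreement the three-camera rig was verified to hold).
#' @return an object of class `sync_report`: `reference_camera`,
#'   `offset_by_camera` (named integer, reference = 0), `max_abs_offset`,
#'   `per_event_residuals` (data.frame `event_id`, `camera`, `residual`),
#'   `passed`.
#' @export
estimate_offsets <- function(anchors, reference, tolerance = 1) {
  anchors <- as.data.frame(anchors, stringsAsFactors = FALSE)
  if (nrow(anchors) == 0) stop_validation("need at least one event anchor")
  if (!all(c("event_id", "camera", "frame") %in% names(anchors))) {
    stop_validation("anchors need columns event_id, camera, frame")
  }
  anchors$frame <- as.integer(anchors$frame)
  by_event <- split(anchors, anchors$event_id)
  if (any(vapply(by_event, nrow, 0L) < 2)) {
    stop_validation("every anchor needs at least two cameras")
  }
  ref_frames <- vapply(by_event, function(ev) {
    i <- match(reference, ev$camera)
    if (is.na(i)) stop_validation("event '", ev$event_id[1],
                                  "' does not include reference camera '",
                                  reference, "'")
    ev$frame[i]
  }, 0L)
  cameras <- unique(anchors$camera)
  cameras <- c(reference, setdiff(cameras, reference))
  diffs <- do.call(rbind, lapply(names(by_event), function(eid) {
    ev <- by_event[[eid]]
    data.frame(event_id = eid, camera = ev$camera,
               diff = ev$frame - ref_frames[[eid]], stringsAsFactors = FALSE)
  }))
  offsets <- vapply(cameras, function(cam) {
    d <- diffs$diff[diffs$camera == cam]
    if (length(d) == 0) {
      warning("camera '", cam, "' appears in no anchor; offset unknown, set to 0")
      return(0L)
    }
    missing_from <- setdiff(names(by_event), diffs$event_id[diffs$camera == cam])
    if (length(missing_from)) {
      warning("camera '", cam, "' missing from anchor(s) ",
              paste(missing_from, collapse = ", "), "; skipped for that camera")
    }
    as.integer(round_half_away(stats::median(d)))
  }, 0L)
  names(offsets) <- cameras
  residuals <- diffs
  residuals$residual <- residuals$diff - offsets[residuals$camera]
  residuals <- residuals[residuals$camera != reference,
                         c("event_id", "camera", "residual")]
  rownames(residuals) <- NULL
  max_abs <- max(abs(offsets))
  structure(list(reference_camera = reference,
                 offset_by_camera = offsets,
                 max_abs_offset = as.integer(max_abs),
                 per_event_residuals = residuals,
                 tolerance = as.integer(tolerance),
                 passed = max_abs <= tolerance && all(residuals$residual == 0)),
            class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("<sync_report> reference %s; offsets: %s; %s\n",
              x$reference_camera,
              paste(names(x$offset_by_camera), x$offset_by_camera,
                    sep = "=", collapse = ", "),
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Verify stream synchronisation
#'
#' `TRUE` iff the largest absolute offset is within `tolerance` frames and
#' every per-event residual is zero (all anchors agree on the offsets).
#'
#' @param report a [sync_report][estimate_offsets].
#' @param tolerance integer frames, default 1.
#' @return logical scalar.
#' @export
verify_sync <- function(report, tolerance = 1) {
  stopifnot(inherits(report, "sync_report"))
  report$max_abs_offset <= tolerance && all(report$per_event_residuals$residual == 0)
}

#' Serialise a sync report to JSON
#'
#' @param report a sync report.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sync_report <- function(report, path) {
  jsonlite::write_json(
    list(reference_camera = report$reference_camera,
         offset_by_camera = as.list(report$offset_by_camera),
         max_abs_offset = report$max_abs_offset,
         per_event_residuals = report$per_event_residuals,
         tolerance = report$tolerance,
         passed = report$passed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
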