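# IoU-threshold matching of model boxes to ground-truth boxes, one frame at
# a time. Matching is one-to-one: each ground-truth box absorbs at most one
# model box and vice versa, reflecting per-animal annotation. Two FP
# conventions are supported because the study's literal FP definition ("a
# box that did not overlap a ground-truth box") leaves boxes with
# 0 < IoU < threshold uncounted, while the usual COCO-style convention
# counts every unmatched model box as FP.

#' Matching configuration
#'
#' @param iou_threshold minimum IoU for a (ground truth, model) pair to count
#'   as a true positive; in `(0, 1]`, default 0.5.
#' @param assignment `"greedy"` (descending-IoU greedy, deterministic
#'   index-based tie-breaks) or `"optimal"` (maximum-cardinality one-to-one
#'   assignment, ties broken by maximum total IoU; exact bitmask dynamic
#'   program).
#' @param fp_mode `"no_overlap"` (default): an unmatched model box is FP only
#'   when it has zero overlap with every ground-truth box, otherwise it is
#'   discarded (neither TP nor FP). `"strict"`: every unmatched model box is
#'   FP.
#' @return an object of class `match_config`.
#' @export
match_config <- function(iou_threshold = 0.5,
                         assignment = c("greedy", "optimal"),
                         fp_mode = c("no_overlap", "strict")) {
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold > 1) {
    stop_validation("iou_threshold must be in (0, 1]")
  }
  structure(list(iou_threshold = iou_threshold,
                 assignment = match.arg(assignment),
                 fp_mode = match.arg(fp_mode)),
            class = "match_config")
}

# Greedy one-to-one assignment: candidate pairs (iou >= thr) sorted by
# descending iou, ties by smaller gt index then smaller model index.
assign_greedy <- function(ious, thr) {
  cand <- which(ious >= thr, arr.ind = TRUE)
  if (nrow(cand) == 0) return(cbind(gt = integer(0), model = integer(0)))
  v <- ious[cand]
  ord <- order(-v, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  gt_used <- logical(max(cand[, 1]))
  md_used <- logical(max(cand[, 2]))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    g <- cand[k, 1]; m <- cand[k, 2]
    if (!gt_used[g] && !md_used[m]) {
      gt_used[g] <- TRUE; md_used[m] <- TRUE; keep[k] <- TRUE
    }
  }
  cbind(gt = cand[keep, 1], model = cand[keep, 2])
}

# Exact assignment maximising (cardinality, total iou) lexicographically.
# Dynamic program over gt rows with a bitmask of used model columns; the
# smaller side is placed on the bitmask, so cost is O(n * 2^min(n, m)).
assign_optimal <- function(ious, thr) {
  n <- nrow(ious); m <- ncol(ious)
  if (n == 0 || m == 0) return(cbind(gt = integer(0), model = integer(0)))
  flipped <- m > n
  A <- if (flipped) t(ious) else ious
  n <- nrow(A); m <- ncol(A)
  if (m > 25) {
    stop_validation("optimal assignment supports at most 25 boxes on the ",
                    "smaller side of a frame; use assignment = 'greedy'")
  }
  BIG <- m + 1 # any extra match beats any total iou difference
  memo <- new.env(parent = emptyenv())
  best <- function(i, mask) {
    if (i > n) return(list(score = 0, pairs = NULL))
    key <- paste0(i, "_", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- best(i + 1, mask) # leave gt row i unmatched
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L && A[i, j] >= thr) {
        sub <- best(i + 1, bitwOr(mask, bit))
        sc <- sub$score + BIG + A[i, j]
        if (sc > res$score) {
          res <- list(score = sc, pairs = rbind(sub$pairs, c(i, j)))
        }
      }
    }
    memo[[key]] <- res
    res
  }
  pairs <- best(1L, 0L)$pairs
  if (is.null(pairs)) return(cbind(gt = integer(0), model = integer(0)))
  if (flipped) pairs <- pairs[, 2:1, drop = FALSE]
  colnames(pairs) <- c("gt", "model")
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' Match one frame's model boxes to its ground-truth boxes
#'
#' Builds the pairwise IoU matrix, assigns pairs with IoU at or above the
#' threshold one-to-one (greedy or optimal), and classifies the remainder:
#' unmatched ground truth is FN; unmatched model boxes are FP or discarded
#' according to `fp_mode` (see [match_config()]).
#'
#' @param gt,model boxes: data.frames with `x_min`/`y_min`/`x_max`/`y_max`
#'   columns, numeric matrices, or `NULL`/empty for none.
#' @param config a [match_config()].
#' @param frame_index integer recorded in the result.
#' @return a list of class `frame_match`: `frame_index`, `pairs` (data.frame
#'   `gt`, `model`, `iou` — row indices into the inputs), `unmatched_gt`,
#'   `unmatched_model`, `discarded_model` (integer index vectors), and the
#'   tallies `tp`, `fp`, `fn`.
#' @export
match_frame <- function(gt, model, config = match_config(), frame_index = 0L) {
  gt_m <- as_box_matrix(gt); model_m <- as_box_matrix(model)
  if (nrow(gt_m)) validate_boxes(gt_m, "ground-truth box")
  if (nrow(model_m)) validate_boxes(model_m, "model box")
  res <- match_boxes_core(gt_m, model_m, config)
  res$frame_index <- as.integer(frame_index)
  class(res) <- "frame_match"
  res
}

# assignment + classification on bare box matrices; no validation, no class
match_boxes_core <- function(gt_m, model_m, config) {
  ious <- iou_matrix(gt_m, model_m)
  pairs <- switch(config$assignment,
                  greedy = assign_greedy(ious, config$iou_threshold),
                  optimal = assign_optimal(ious, config$iou_threshold))
  matched_gt <- pairs[, 1]
  matched_md <- pairs[, 2]
  unmatched_gt <- setdiff(seq_len(nrow(gt_m)), matched_gt)
  free_md <- setdiff(seq_len(nrow(model_m)), matched_md)
  if (config$fp_mode == "strict" || nrow(gt_m) == 0) {
    fp_md <- free_md
    discarded <- integer(0)
  } else {
    # literal reading: FP only if the model box overlaps no ground truth at all
    max_overlap <- if (length(free_md)) {
      apply(ious[, free_md, drop = FALSE], 2, max)
    } else numeric(0)
    fp_md <- free_md[max_overlap == 0]
    discarded <- free_md[max_overlap > 0]
  }
  list(pairs = data.frame(gt = matched_gt, model = matched_md,
                          iou = if (nrow(pairs)) ious[pairs] else numeric(0)),
       unmatched_gt = unmatched_gt,
       unmatched_model = fp_md,
       discarded_model = discarded,
       tp = nrow(pairs), fp = length(fp_md), fn = length(unmatched_gt))
}

#' Match two aligned detection streams frame by frame
#'
#' Sums per-frame TP/FP/FN over the common frame range and concatenates the
#' matched-pair IoUs in frame order. Both sets must already be on a common
#' timeline and clipped to the same frame range ([apply_offset()] then
#' [clip_to_frame_range()]).
#'
#' @param gt_set ground-truth [detection_set].
#' @param model_set model [detection_set].
#' @param config a [match_config()].
#' @param keep_frames if `TRUE`, the per-frame [match_frame()] results are
#'   kept in the `frames` element (memory-proportional to the sequence).
#' @return an object of class `match_counts`: `tp`, `fp`, `fn`,
#'   `matched_ious`, `n_gt`, `n_model`, and optionally `frames`.
#' @export
match_sequence <- function(gt_set, model_set, config = match_config(),
                           keep_frames = FALSE) {
  validate_detection_set(gt_set)
  validate_detection_set(model_set)
  if (!identical(gt_set$frame_range, model_set$frame_range)) {
    stop_validation("frame ranges differ ([", gt_set$frame_range[1], ", ",
                    gt_set$frame_range[2], "] vs [", model_set$frame_range[1],
                    ", ", model_set$frame_range[2],
                    "]); clip both sets to a common range first")
  }
  gt_d <- gt_set$detections[gt_set$detections$source == "ground_truth", , drop = FALSE]
  md_d <- model_set$detections[model_set$detections$source == "model", , drop = FALSE]
  gt_boxes <- as.matrix(gt_d[BOX_COLS])
  md_boxes <- as.matrix(md_d[BOX_COLS])
  gt_by_frame <- split(seq_len(nrow(gt_d)), gt_d$frame)
  md_by_frame <- split(seq_len(nrow(md_d)), md_d$frame)
  frames <- sort(unique(c(gt_d$frame, md_d$frame)))
  tp <- fp <- fn <- 0L
  ious_acc <- vector("list", length(frames))
  frame_results <- if (keep_frames) vector("list", length(frames)) else NULL
  for (k in seq_along(frames)) {
    f <- as.character(frames[k])
    gi <- gt_by_frame[[f]]
    mi <- md_by_frame[[f]]
    fm <- match_boxes_core(gt_boxes[gi, , drop = FALSE],
                           md_boxes[mi, , drop = FALSE], config)
    tp <- tp + fm$tp; fp <- fp + fm$fp; fn <- fn + fm$fn
    ious_acc[[k]] <- fm$pairs$iou
    if (keep_frames) {
      # translate frame-local row indices back to detection ids for the dump
      fm$frame_index <- frames[k]
      fm$gt_ids <- gt_d$id[gi]
      fm$model_rows <- mi
      class(fm) <- "frame_match"
      frame_results[[k]] <- fm
    }
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 matched_ious = unlist(ious_acc) %||% numeric(0),
                 n_gt = nrow(gt_d), n_model = nrow(md_d),
                 frames = frame_results),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("<match_counts> TP %d, FP %d, FN %d (%d ground-truth, %d model boxes)\n",
              x$tp, x$fp, x$fn, x$n_gt, x$n_model))
  invisible(x)
}

#' Dump per-frame match details to CSV
#'
#' Writes `frame,kind,gt_id,model_row,iou` with `kind` in
#' `{TP, FP, FN, DISCARDED}`. Requires `match_sequence(..., keep_frames =
#' TRUE)`.
#'
#' @param counts a [match_counts][match_sequence] with per-frame results.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_match_details <- function(counts, path) {
  stopifnot(inherits(counts, "match_counts"))
  if (is.null(counts$frames)) {
    stop_validation("per-frame results not kept; rerun match_sequence with keep_frames = TRUE")
  }
  rows <- lapply(counts$frames, function(fm) {
    out <- list()
    if (nrow(fm$pairs)) {
      out$tp <- data.frame(frame = fm$frame_index, kind = "TP",
                           gt_id = fm$gt_ids[fm$pairs$gt],
                           model_row = fm$model_rows[fm$pairs$model],
                           iou = fm$pairs$iou)
    }
    if (length(fm$unmatched_gt)) {
      out$fn <- data.frame(frame = fm$frame_index, kind = "FN",
                           gt_id = fm$gt_ids[fm$unmatched_gt],
                           model_row = NA_integer_, iou = NA_real_)
    }
    if (length(fm$unmatched_model)) {
      out$fp <- data.frame(frame = fm$frame_index, kind = "FP",
                           gt_id = NA_character_,
                           model_row = fm$model_rows[fm$unmatched_model],
                           iou = NA_real_)
    }
    if (length(fm$discarded_model)) {
      out$disc <- data.frame(frame = fm$frame_index, kind = "DISCARDED",
                             gt_id = NA_character_,
                             model_row = fm$model_rows[fm$discarded_model],
                             iou = NA_real_)
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(frame = integer(0), kind = character(0),
                       gt_id = character(0), model_row = integer(0),
                       iou = numeric(0))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
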