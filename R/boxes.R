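# Axis-aligned boxes are rows of a numeric matrix/data.frame with columns
# x_min, y_min, x_max, y_max; pixel coordinates, origin top-left, y downward.

BOX_COLS <- c("x_min", "y_min", "x_max", "y_max")

as_box_matrix <- function(boxes) {
  if (is.null(boxes) || (is.data.frame(boxes) && nrow(boxes) == 0)) {
    return(matrix(numeric(0), ncol = 4, dimnames = list(NULL, BOX_COLS)))
  }
  if (is.numeric(boxes) && is.null(dim(boxes))) {
    if (length(boxes) != 4) stop_validation("a single box needs 4 coordinates")
    boxes <- matrix(boxes, ncol = 4)
  }
  if (is.data.frame(boxes)) {
    if (!all(BOX_COLS %in% names(boxes))) {
      stop_validation("box data must have columns ", paste(BOX_COLS, collapse = ", "))
    }
    boxes <- as.matrix(boxes[BOX_COLS])
  }
  colnames(boxes) <- BOX_COLS
  boxes
}

validate_boxes <- function(boxes, what = "box") {
  b <- as_box_matrix(boxes)
  bad <- b[, "x_min"] >= b[, "x_max"] | b[, "y_min"] >= b[, "y_max"]
  if (any(bad)) {
    stop_validation(what, " ", which(bad)[1],
                    " is degenerate: x_min < x_max and y_min < y_max required")
  }
  invisible(b)
}

box_area <- function(boxes) {
  b <- as_box_matrix(boxes)
  (b[, "x_max"] - b[, "x_min"]) * (b[, "y_max"] - b[, "y_min"])
}

#' Intersection over union of two boxes
#'
#' Ratio of overlap area to union area of two axis-aligned boxes. 1 for
#' identical boxes, 0 when disjoint; symmetric in its arguments and invariant
#' to rescaling both boxes by a common positive factor.
#'
#' @param a,b length-4 numeric vectors `(x_min, y_min, x_max, y_max)` or
#'   single-row box data.
#' @return a number in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 10, 10), c(0, 5, 10, 15)) # 1/3
#' @export
iou <- function(a, b) {
  a <- validate_boxes(a); b <- validate_boxes(b)
  drop(iou_matrix(a, b))
}

# n_a x n_b matrix of pairwise IoUs, vectorised over both sets
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(numeric(0), nrow = na, ncol = nb))
  ix <- pmin(rep(a[, "x_max"], nb), rep(b[, "x_max"], each = na)) -
        pmax(rep(a[, "x_min"], nb), rep(b[, "x_min"], each = na))
  iy <- pmin(rep(a[, "y_max"], nb), rep(b[, "y_max"], each = na)) -
        pmax(rep(a[, "y_min"], nb), rep(b[, "y_min"], each = na))
  inter <- pmax(ix, 0) * pmax(iy, 0)
  union <- rep(box_area(a), nb) + rep(box_area(b), each = na) - inter
  matrix(inter / union, nrow = na, ncol = nb)
}
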