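#' Axis-aligned bounding boxes
#'
#' Boxes are stored in corner format `(x1, y1, x2, y2)` with `x2 >= x1` and
#' `y2 >= y1`, either in absolute pixel coordinates or normalized to the unit
#' square. All loss and metric code in the package accepts either a length-4
#' numeric vector (one box) or an `n x 4` matrix (one box per row).
#'
#' @param x1,y1,x2,y2 numeric vectors of corner coordinates.
#' @param frame `"absolute"` (pixels) or `"normalized"` (unit square).
#' @return an `n x 4` numeric matrix of class `palm_box` with a `frame`
#'   attribute and columns `x1, y1, x2, y2`.
#' @examples
#' b <- box(0, 0, 2, 2)
#' box_area(b)
#' @export
box <- function(x1, y1, x2, y2, frame = c("absolute", "normalized")) {
  frame <- match.arg(frame)
  m <- cbind(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  if (any(!is.finite(m))) stop("box coordinates must be finite")
  if (any(m[, 3] < m[, 1]) || any(m[, 4] < m[, 2]))
    stop("invalid box: needs x2 >= x1 and y2 >= y1")
  if (frame == "normalized" && (any(m < 0) || any(m > 1)))
    stop("normalized boxes must lie in [0, 1]")
  structure(m, class = c("palm_box", "matrix"), frame = frame)
}

# coerce to an n x 4 matrix without validation overhead (internal hot path)
as_box_matrix <- function(b) {
  if (is.matrix(b)) {
    stopifnot(ncol(b) == 4)
    b
  } else {
    stopifnot(length(b) == 4)
    matrix(b, ncol = 4)
  }
}

#' @rdname box
#' @param b a box vector or matrix.
#' @export
box_area <- function(b) {
  b <- as_box_matrix(b)
  pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
}

#' @rdname box
#' @export
box_center <- function(b) {
  b <- as_box_matrix(b)
  cbind(cx = (b[, 1] + b[, 3]) / 2, cy = (b[, 2] + b[, 4]) / 2)
}

#' @rdname box
#' @export
box_wh <- function(b) {
  b <- as_box_matrix(b)
  cbind(w = b[, 3] - b[, 1], h = b[, 4] - b[, 2])
}

#' Convert between corner and center parameterizations
#'
#' `cxcywh` is the `(center_x, center_y, width, height)` layout used by the
#' query decoder; `xyxy` is the corner layout used everywhere else;
#' `xywh` is the COCO on-disk layout (top-left corner plus size).
#'
#' @param m an `n x 4` matrix (or length-4 vector) in the source layout.
#' @return an `n x 4` matrix in the target layout.
#' @export
cxcywh_to_xyxy <- function(m) {
  m <- as_box_matrix(m)
  cbind(m[, 1] - m[, 3] / 2, m[, 2] - m[, 4] / 2,
        m[, 1] + m[, 3] / 2, m[, 2] + m[, 4] / 2)
}

#' @rdname cxcywh_to_xyxy
#' @export
xyxy_to_cxcywh <- function(m) {
  m <- as_box_matrix(m)
  cbind((m[, 1] + m[, 3]) / 2, (m[, 2] + m[, 4]) / 2,
        m[, 3] - m[, 1], m[, 4] - m[, 2])
}

#' @rdname cxcywh_to_xyxy
#' @export
xywh_to_xyxy <- function(m) {
  m <- as_box_matrix(m)
  cbind(m[, 1], m[, 2], m[, 1] + m[, 3], m[, 2] + m[, 4])
}

#' @rdname cxcywh_to_xyxy
#' @export
xyxy_to_xywh <- function(m) {
  m <- as_box_matrix(m)
  cbind(m[, 1], m[, 2], m[, 3] - m[, 1], m[, 4] - m[, 2])
}

#' Rescale a box about its own center
#'
#' Used by the inner-IoU computation: both boxes are shrunk (`ratio < 1`) or
#' expanded (`ratio > 1`) about their centers before the overlap is measured.
#'
#' @param b box vector or matrix.
#' @param ratio positive scale factor.
#' @export
box_rescale_about_center <- function(b, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1 || !is.finite(ratio) || ratio <= 0)
    stop("ratio must be a positive finite scalar")
  b <- as_box_matrix(b)
  ctr <- box_center(b)
  wh <- box_wh(b) * ratio
  cbind(ctr[, 1] - wh[, 1] / 2, ctr[, 2] - wh[, 2] / 2,
        ctr[, 1] + wh[, 1] / 2, ctr[, 2] + wh[, 2] / 2)
}

#' Pairwise IoU matrix between two box sets
#'
#' @param a `n x 4`, `b` `m x 4` corner-format matrices.
#' @return an `n x m` matrix of IoU values in `[0, 1]`.
#' @export
box_iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ix1 <- outer(a[, 1], b[, 1], pmax)
  iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin)
  iy2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  uni <- outer(box_area(a), box_area(b), "+") - inter
  out <- matrix(0, n, m)
  pos <- uni > 0
  out[pos] <- inter[pos] / uni[pos]
  out
}

#' Clip boxes to an image extent
#' @param b box matrix, `w,h` image width and height.
#' @export
box_clip <- function(b, w, h) {
  b <- as_box_matrix(b)
  cbind(pmin(pmax(b[, 1], 0), w), pmin(pmax(b[, 2], 0), h),
        pmin(pmax(b[, 3], 0), w), pmin(pmax(b[, 4], 0), h))
}
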