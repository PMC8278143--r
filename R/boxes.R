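#' Intersection over union of bounding boxes
#'
#' Boxes are axis-aligned rectangles in half-open pixel coordinates
#' \code{[x_min, x_max) x [y_min, y_max)}. The IoU of two boxes is the area
#' of their intersection divided by the area of their union: 0 for disjoint
#' boxes, 1 exactly when they coincide. \code{boxIoU} is vectorized
#' elementwise over its arguments; \code{iouMatrix} returns the full
#' cross-IoU matrix of two box sets.
#'
#' @param a,b data.frames (or single rows) with columns \code{x_min, y_min,
#'   x_max, y_max}.
#' @return \code{boxIoU}: numeric vector of IoU values in [0, 1].
#'   \code{iouMatrix}: an \code{nrow(a) x nrow(b)} matrix.
#' @examples
#' a <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' b <- data.frame(x_min = 5, y_min = 0, x_max = 15, y_max = 10)
#' boxIoU(a, b)  # 50 / 150
#' @export
boxIoU <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

#' @rdname boxIoU
#' @export
iouMatrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ix <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  iy <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (outer(area_a, area_b, "+") - inter)
}

#' Non-maximum suppression
#'
#' Greedy class-agnostic suppression of overlapping detections: boxes are
#' visited in order of decreasing confidence; a box is kept unless its IoU
#' with an already-kept box is at least \code{iou_threshold}. Any surviving
#' pair therefore has IoU strictly below the threshold.
#'
#' @param objects data.frame of detections with box columns and
#'   \code{confidence}.
#' @param iou_threshold suppression threshold in (0, 1].
#' @return The surviving rows of \code{objects}, in decreasing confidence
#'   order. Confidence ties are broken by input order.
#' @examples
#' d <- data.frame(x_min = c(0, 0), y_min = c(0, 0),
#'                 x_max = c(10, 10), y_max = c(10, 10),
#'                 confidence = c(0.9, 0.8))
#' nms(d, 0.5)  # only the 0.9 box survives
#' @export
nms <- function(objects, iou_threshold) {
  if (!is.numeric(iou_threshold) || length(iou_threshold) != 1L ||
      iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be a single number in (0, 1]")
  n <- nrow(objects)
  if (!n) return(objects)
  ord <- order(-objects$confidence, seq_len(n))
  iom <- iouMatrix(objects, objects)
  keep <- logical(n)
  for (i in ord) {
    if (!any(keep & iom[, i] >= iou_threshold)) keep[i] <- TRUE
  }
  out <- objects[ord[keep[ord]], , drop = FALSE]
  rownames(out) <- NULL
  out
}
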