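#' Construct a bounding box
#'
#' Boxes use pixel units with the origin at the image top-left corner, x
#' increasing rightward and y downward, and are stored as
#' `(left, top, width, height)`. Intervals are half-open at the pixel grid,
#' matching the MOTChallenge CSV convention used throughout the package.
#'
#' @param left,top Coordinates of the top-left corner, in pixels.
#' @param width,height Box size in pixels; both must be strictly positive.
#' @return A named numeric vector of length 4 with names
#'   `left`, `top`, `width`, `height`.
#' @examples
#' box(0, 0, 10, 20)
#' @export
box <- function(left, top, width, height) {
  v <- c(left = as.numeric(left), top = as.numeric(top),
         width = as.numeric(width), height = as.numeric(height))
  if (!all(is.finite(v))) stop("box coordinates must be finite")
  if (v[["width"]] <= 0 || v[["height"]] <= 0)
    stop("box width and height must be strictly positive")
  v
}

#' Center of a bounding box
#'
#' @param b A box as returned by [box()], or any numeric vector with
#'   `left`, `top`, `width`, `height` in the first four positions.
#' @return Named numeric vector `c(x, y)`: the box center in pixels.
#' @examples
#' box_center(box(3, 4, 4, 6)) # (5, 7)
#' @export
box_center <- function(b) {
  c(x = b[[1]] + b[[3]] / 2, y = b[[2]] + b[[4]] / 2)
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as returned by [box()].
#' @return IOU in `[0, 1]`; 0 for disjoint boxes, 1 for identical boxes.
#' @examples
#' iou(box(0, 0, 10, 10), box(5, 0, 10, 10)) # 1/3
#' @export
iou <- function(a, b) {
  ix <- min(a[[1]] + a[[3]], b[[1]] + b[[3]]) - max(a[[1]], b[[1]])
  iy <- min(a[[2]] + a[[4]], b[[2]] + b[[4]]) - max(a[[2]], b[[2]])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (a[[3]] * a[[4]] + b[[3]] * b[[4]] - inter)
}

#' Pairwise IOU matrix between two sets of boxes
#'
#' @param a,b Numeric matrices with columns `left`, `top`, `width`, `height`
#'   (one box per row).
#' @return A `nrow(a)` by `nrow(b)` matrix of IOU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  ar <- a[, 1] + a[, 3]; ab <- a[, 2] + a[, 4]
  br <- b[, 1] + b[, 3]; bb <- b[, 2] + b[, 4]
  ix <- outer(ar, br, pmin) - outer(a[, 1], b[, 1], pmax)
  iy <- outer(ab, bb, pmin) - outer(a[, 2], b[, 2], pmax)
  inter <- pmax(ix, 0) * pmax(iy, 0)
  union <- outer(a[, 3] * a[, 4], b[, 3] * b[, 4], "+") - inter
  inter / union
}

# coerce data.frame / vector / matrix to an n x 4 box matrix
as_box_matrix <- function(x) {
  if (is.data.frame(x))
    x <- as.matrix(x[, c("left", "top", "width", "height")])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

#' Appearance descriptor: normalized flattened 10x10 crop
#'
#' Extracts the lightweight appearance feature used by the tracker: the box
#' region is cropped from a grayscale frame, resized to 10x10 with bilinear
#' interpolation, flattened row-major to a 100-vector, and scaled to unit
#' Euclidean norm (an all-black crop stays all-zero). This replaces the deep
#' CNN embedding of conventional appearance-based trackers with a descriptor
#' cheap enough for embedded hardware.
#'
#' @param frame Numeric matrix, the grayscale image indexed `[y, x]` with
#'   intensities in `[0, 1]` (values above 1 are assumed 8-bit and divided
#'   by 255).
#' @param b A box ([box()]); it is clipped to the frame bounds and must
#'   retain positive area.
#' @return Numeric vector of length 100 with Euclidean norm 1 (or all zero).
#' @examples
#' f <- matrix(0.5, 40, 40)
#' v <- extract_feature(f, box(5, 5, 20, 20))
#' all.equal(v, rep(0.1, 100))
#' @export
extract_feature <- function(frame, b) {
  stopifnot(is.matrix(frame))
  if (max(frame) > 1) frame <- frame / 255
  ny <- nrow(frame); nx <- ncol(frame)
  x0 <- max(0, floor(b[[1]])); x1 <- min(nx, ceiling(b[[1]] + b[[3]]))
  y0 <- max(0, floor(b[[2]])); y1 <- min(ny, ceiling(b[[2]] + b[[4]]))
  if (x1 <= x0 || y1 <= y0)
    stop("invalid detection: box lies entirely outside the frame")
  crop <- frame[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  small <- EBImage::resize(crop, w = 10L, h = 10L, filter = "bilinear")
  v <- as.vector(t(small))  # row-major over the [y, x] crop
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v <- v / nrm
  v
}

#' Flat (appearance-free) descriptor
#'
#' The unit-norm constant 100-vector used when no frame pixels are available
#' for a detection. All such features have cosine distance 0 to each other,
#' so association degenerates to motion gating plus assignment cost order,
#' which is the intended behaviour for visually indistinguishable animals.
#'
#' @return Numeric vector of length 100, every entry `0.1`.
#' @export
flat_feature <- function() rep(0.1, 100)
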