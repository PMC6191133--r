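## Planar geometry primitives used by the quantification pipeline.
## Coordinates are 0-based pixel positions (origin top-left, x rightward,
## y downward); nothing here depends on that convention beyond naming.

.closePoly <- function(p) rbind(p, p[1, , drop = FALSE])

## orientation of the triplet (a, b, c): > 0 counter-clockwise in a
## y-up frame, < 0 clockwise, 0 collinear
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.segIntersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) return(TRUE)
  onSeg <- function(p, q, r) {  # collinear r on segment pq
    min(p[1], q[1]) - eps <= r[1] && r[1] <= max(p[1], q[1]) + eps &&
    min(p[2], q[2]) - eps <= r[2] && r[2] <= max(p[2], q[2]) + eps
  }
  (abs(d1) <= eps && onSeg(p3, p4, p1)) ||
  (abs(d2) <= eps && onSeg(p3, p4, p2)) ||
  (abs(d3) <= eps && onSeg(p1, p2, p3)) ||
  (abs(d4) <= eps && onSeg(p1, p2, p4))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Non-adjacent edges must not intersect or touch; consecutive duplicate
#' vertices are rejected.
#'
#' @param polygon numeric n x 2 matrix of vertices (not closed).
#' @return logical(1)
#' @export
isSimplePolygon <- function(polygon) {
  p <- as.matrix(polygon)
  n <- nrow(p)
  if (n < 3L || ncol(p) != 2L || anyNA(p)) return(FALSE)
  nxt <- c(2:n, 1L)
  if (any(p[, 1] == p[nxt, 1] & p[, 2] == p[nxt, 2])) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ## skip adjacent edges (share a vertex), incl. the (1, n) wrap pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segIntersect(p[i, ], p[nxt[i], ], p[j, ], p[nxt[j], ])) return(FALSE)
    }
  }
  TRUE
}

.checkPolygon <- function(polygon) {
  p <- as.matrix(polygon)
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 3L)
    invalidGeometry("a polygon needs at least 3 (x, y) vertices")
  if (!isSimplePolygon(p))
    invalidGeometry("polygon is self-intersecting or degenerate")
  storage.mode(p) <- "double"
  p
}

#' Absolute polygon area by the shoelace formula
#'
#' Vertex orientation (clockwise or counter-clockwise) does not matter.
#'
#' @param polygon numeric n x 2 matrix of vertices of a simple polygon.
#' @return area in squared input units (px^2 for pixel coordinates).
#' @examples
#' polygonArea(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygonArea <- function(polygon) {
  p <- .checkPolygon(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Point-in-polygon test (ray casting, boundary inclusive)
#'
#' Points exactly on an edge or vertex count as inside.
#'
#' @param point numeric length-2 (x, y), or an n x 2 matrix of points.
#' @param polygon numeric m x 2 matrix of vertices of a simple polygon.
#' @param eps boundary tolerance.
#' @return logical, one value per point.
#' @export
pointInPolygon <- function(point, polygon, eps = 1e-9) {
  p <- .checkPolygon(polygon)
  pts <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  px <- as.numeric(pts[, 1]); py <- as.numeric(pts[, 2])
  n <- nrow(p)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    ## boundary: squared distance from point to segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
    d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
    onEdge <- onEdge | d2 <= eps^2
    ## crossing test (half-open rule so shared vertices count once)
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Count detected cells whose centre lies in a region polygon
#'
#' Membership is decided by the circle centre only; discs are not clipped
#' at the polygon border.
#'
#' @param detections a [CellDetectionSet-class].
#' @param polygon numeric n x 2 matrix, simple polygon.
#' @return integer count.
#' @export
countCellsInRegion <- function(detections, polygon) {
  stopifnot(is(detections, "CellDetectionSet"))
  cc <- centres(detections)
  if (nrow(cc) == 0L) {
    .checkPolygon(polygon)  # still propagate invalid geometry
    return(0L)
  }
  sum(pointInPolygon(cc, polygon))
}

#' Net capped area of one annotated region
#'
#' Subtracts one effective-radius disc per detected uncapped cell inside
#' the polygon from the gross polygon area; the result is clamped at zero
#' (a clamp is reported via a condition message at the `message` level
#' carrying the raw value). With fewer than two detections no effective
#' radius exists and nothing is subtracted.
#'
#' @param polygon numeric n x 2 matrix, simple polygon.
#' @param detections a [CellDetectionSet-class].
#' @return area in px^2.
#' @export
cappedArea <- function(polygon, detections) {
  a <- polygonArea(polygon)
  r <- effectiveRadius(detections)
  if (is.na(r)) return(a)
  n <- countCellsInRegion(detections, polygon)
  raw <- a - n * pi * r^2
  if (raw < 0) {
    message(sprintf("capped area clamped to 0 (raw value %.2f px^2)", raw))
    return(0)
  }
  raw
}

#' Convert a pixel area to physical units via the inner-frame quadrilateral
#'
#' The scale factor is the ratio of the known physical inner-frame area to
#' the pixel area of the annotated inner-corner quadrilateral; photographs
#' are assumed to be taken perpendicular to the frame, so no perspective
#' rectification is applied.
#'
#' @param areaPx2 area in px^2.
#' @param innerCorners 4 x 2 matrix of inner-frame corners.
#' @param innerFrameCm2 physical inner-frame area in cm^2.
#' @return area in cm^2.
#' @export
scaleToPhysical <- function(areaPx2, innerCorners, innerFrameCm2) {
  aIn <- polygonArea(innerCorners)
  if (aIn <= 0) invalidGeometry("degenerate inner quadrilateral")
  areaPx2 * innerFrameCm2 / aIn
}
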