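# Planar geometry primitives used by the landscape and connectivity modules.
# All coordinates are projected metres; polygons are n x 2 matrices (implicitly
# closed), polylines are lists of n x 2 matrices.

#' Convert a list of polylines to a segment matrix
#'
#' @param lines list of numeric matrices with columns x, y (each a polyline
#'   with at least two vertices).
#' @return numeric matrix with columns `x1, y1, x2, y2`, one row per segment.
#' @keywords internal
polylines_to_segments <- function(lines) {
  if (length(lines) == 0L) {
    return(matrix(numeric(0), ncol = 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  }
  segs <- lapply(lines, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2L) return(NULL)
    cbind(m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2])
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  colnames(segs) <- c("x1", "y1", "x2", "y2")
  segs
}

# Drop duplicate segments regardless of orientation (used when informal trails
# overlap the formal network).
dedupe_segments <- function(segs, tol = 1e-9) {
  if (nrow(segs) == 0L) return(segs)
  a <- round(segs / tol) * tol
  swap <- a[, 1] > a[, 3] | (a[, 1] == a[, 3] & a[, 2] > a[, 4])
  canon <- a
  canon[swap, ] <- a[swap, c(3, 4, 1, 2)]
  key <- paste(canon[, 1], canon[, 2], canon[, 3], canon[, 4], sep = "|")
  segs[!duplicated(key), , drop = FALSE]
}

#' Minimum distance from points to a set of segments
#'
#' @param px,py numeric vectors of point coordinates.
#' @param segs segment matrix as from [polylines_to_segments()].
#' @return numeric vector of distances (Inf when `segs` is empty).
#' @keywords internal
dist_point_segments <- function(px, py, segs) {
  n <- length(px)
  if (nrow(segs) == 0L) return(rep(Inf, n))
  out <- rep(Inf, n)
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((px - x1)^2 + (py - y1)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
    }
    out <- pmin(out, d)
  }
  out
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' Points exactly on an edge may fall on either side; the landscape generator
#' never places geometry on cell-centre lattice points, so this does not
#' matter in practice.
#'
#' @param px,py numeric vectors.
#' @param poly n x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

# Orientation of triplet (sign of cross product); 0 = collinear.
.orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sign(v)
}

#' Do two segments intersect?
#'
#' Endpoint touches and collinear overlap count as intersection, matching the
#' transect-crossing convention (a step that lands exactly on the line has
#' crossed it).
#'
#' @param p1,p2 numeric length-2 endpoints of the first segment.
#' @param q1,q2 numeric length-2 endpoints of the second segment.
#' @return logical scalar.
#' @keywords internal
segments_intersect <- function(p1, p2, q1, q2) {
  o1 <- .orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  o2 <- .orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  o3 <- .orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  o4 <- .orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(ax, ay, bx, by, px, py) {
    .orient(ax, ay, bx, by, px, py) == 0 &&
      px >= min(ax, bx) - 1e-12 && px <= max(ax, bx) + 1e-12 &&
      py >= min(ay, by) - 1e-12 && py <= max(ay, by) + 1e-12
  }
  on_seg(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2]) ||
    on_seg(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2]) ||
    on_seg(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2]) ||
    on_seg(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
}

#' Length of a segment inside a circle
#'
#' Exact clipping of segment (x1,y1)-(x2,y2) against the disc of radius `r`
#' centred at (cx, cy). Used by the line-density layer so that the analytic
#' chord example (a line through a cell centre) holds exactly.
#'
#' @return numeric scalar, clipped length in the same units as the inputs.
#' @keywords internal
seg_length_in_circle <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  fx <- x1 - cx; fy <- y1 - cy
  a <- dx * dx + dy * dy
  if (a == 0) return(0)
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t1 <- max(0, (-b - sq) / (2 * a))
  t2 <- min(1, (-b + sq) / (2 * a))
  if (t2 <= t1) return(0)
  (t2 - t1) * sqrt(a)
}

# Vectorised variant of seg_length_in_circle over many circle centres.
.seg_len_in_circles <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx * dx + dy * dy
  if (a == 0) return(rep(0, length(cx)))
  fx <- x1 - cx; fy <- y1 - cy
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  out <- numeric(length(cx))
  pos <- disc > 0
  if (any(pos)) {
    sq <- sqrt(disc[pos])
    t1 <- pmax(0, (-b[pos] - sq) / (2 * a))
    t2 <- pmin(1, (-b[pos] + sq) / (2 * a))
    out[pos] <- pmax(0, t2 - t1) * sqrt(a)
  }
  out
}

# Bounding box of a polygon or polyline matrix.
.bbox <- function(m) c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
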