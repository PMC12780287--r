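# Low-level planar polygon utilities.  All coordinates are millimetres in the
# image plane; pixel (0,0) has its *center* at the origin, x runs along
# columns and y along rows.  Inclusion uses the even-odd (crossing) rule
# evaluated at voxel centers throughout the package.

#' Test points against a polygon (even-odd rule)
#'
#' Vectorized crossing-number test. Points exactly on an edge may fall on
#' either side; the phantom generator keeps contours off voxel centers so the
#' rule is deterministic in practice.
#'
#' @param px,py numeric vectors of point coordinates (mm).
#' @param poly two-column matrix of polygon vertices (x, y) in mm; the
#'   polygon is closed implicitly.
#' @return logical vector, `TRUE` where the point lies inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as_poly(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

as_poly <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("a polygon needs a two-column (x, y) matrix with >= 3 vertices")
  storage.mode(poly) <- "double"
  # drop a duplicated closing vertex
  if (all(poly[1L, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

#' Shoelace area of a polygon (mm^2)
#' @inheritParams point_in_polygon
#' @export
polygon_area <- function(poly) {
  poly <- as_poly(poly)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Minimum Euclidean distance from points to a polygon boundary (mm)
#' @inheritParams point_in_polygon
#' @return numeric vector of distances (0 for points on the boundary).
#' @export
dist_to_polygon <- function(px, py, poly) {
  poly <- as_poly(poly)
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- poly[j, 1L]; y1 <- poly[j, 2L]
    x2 <- poly[i, 1L]; y2 <- poly[i, 2L]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
    ex <- px - (x1 + t * dx)
    ey <- py - (y1 + t * dy)
    d2 <- pmin(d2, ex * ex + ey * ey)
    j <- i
  }
  sqrt(d2)
}

#' Is a polygon simple (non-self-intersecting)?
#'
#' Checks every pair of non-adjacent edges for proper crossings.
#'
#' @inheritParams point_in_polygon
#' @export
polygon_is_simple <- function(poly) {
  poly <- as_poly(poly)
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  ax <- poly[, 1L]; ay <- poly[, 2L]
  bx <- poly[nxt, 1L]; by <- poly[nxt, 2L]
  orient <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  for (a in seq_len(n - 2L)) {
    b <- (a + 2L):n
    if (a == 1L) b <- b[b != n]  # wrap-around pair shares a vertex
    o1 <- orient(ax[a], ay[a], bx[a], by[a], ax[b], ay[b])
    o2 <- orient(ax[a], ay[a], bx[a], by[a], bx[b], by[b])
    o3 <- orient(ax[b], ay[b], bx[b], by[b], ax[a], ay[a])
    o4 <- orient(ax[b], ay[b], bx[b], by[b], bx[a], by[a])
    hit <- ((o1 > 0) != (o2 > 0)) & ((o3 > 0) != (o4 > 0)) &
      o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' Regular polygon approximating a circle
#'
#' @param cx,cy center (mm).
#' @param r radius (mm).
#' @param n number of vertices.
#' @return two-column vertex matrix.
#' @export
circle_polygon <- function(cx, cy, r, n = 128L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Trace a binary in-plane voxel set into closed polygons along the 0.5 level
# set (marching squares via contourLines).  Coordinates come out in mm.
# Re-rasterizing with the voxel-center rule reproduces the set.
trace_voxel_outline <- function(bin, spacing) {
  nr <- nrow(bin); nc <- ncol(bin)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- bin * 1
  # contourLines treats x as rows of z; feed transposed-free by mapping:
  # x-axis of z rows -> our y (rows), y-axis -> our x (cols)
  ys <- ((0:(nr + 1L)) - 1) * spacing[1L]
  xs <- ((0:(nc + 1L)) - 1) * spacing[2L]
  cl <- grDevices::contourLines(ys, xs, z, levels = 0.5)
  lapply(cl, function(l) cbind(x = l$y, y = l$x))
}
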