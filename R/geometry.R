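# Planar polygon helpers. All geometry in this package is planar: synthetic
# regions are generated in a km frame, and real-data users are expected to
# pre-project to a planar CRS before ingest.

#' Planar (shoelace) area of a polygon ring
#'
#' @param ring Two-column numeric matrix of vertices (x, y). The ring may be
#'   open or explicitly closed; closure is implied.
#' @return Non-negative area in squared coordinate units.
#' @keywords internal
polygon_area <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

polygon_centroid <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) {
    return(c(mean(x[-n]), mean(y[-n])))
  }
  cx <- sum((x[-n] + x[-1]) * cross) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cross) / (6 * a)
  c(cx, cy)
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
    abort("a polygon ring needs a two-column numeric matrix with >= 3 vertices")
  }
  if (any(ring[1, ] != ring[nrow(ring), ])) {
    ring <- rbind(ring, ring[1, ])
  }
  ring
}

#' Even-odd ray-casting point-in-polygon test, boundary inclusive
#'
#' Vectorized over points: a point is inside when a horizontal ray to the
#' right crosses the boundary an odd number of times, and points lying exactly
#' on an edge or vertex count as inside.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param ring Two-column vertex matrix (closed or open).
#' @return Logical vector, one entry per point.
#' @keywords internal
points_in_ring <- function(px, py, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    # boundary test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) < 1e-12 * (1 + abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    # even-odd crossing: edge straddles the horizontal line at py
    straddles <- (y1 > py) != (y2 > py)
    if (any(straddles)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crosses <- straddles & (px < xint)
      inside <- xor(inside, crosses)
    }
  }
  inside | on_edge
}

ring_bbox <- function(ring) {
  c(
    xmin = min(ring[, 1]), xmax = max(ring[, 1]),
    ymin = min(ring[, 2]), ymax = max(ring[, 2])
  )
}
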