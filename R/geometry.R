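#' Feret (caliper) diameters of a 2-D point set
#'
#' Computes the maximum and minimum caliper widths of the convex hull of a
#' point cloud. The maximum Feret diameter is the largest pairwise distance
#' between hull vertices (which equals the largest pairwise distance over the
#' full set); the minimum Feret diameter is the smallest width over directions
#' normal to hull edges, which is exact for convex polygons.
#'
#' @param points two-column numeric matrix of (x, y) coordinates.
#' @return list with `max`, `min` (both in the units of `points`) and `hull`,
#'   the hull vertices in order (two-column matrix).
#' @examples
#' sq <- cbind(c(0, 4, 4, 0), c(0, 0, 2, 2))
#' feret_calipers(sq) # max = sqrt(20), min = 2
#' @export
feret_calipers <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 1L)
    stop("`points` must be an n x 2 matrix with n >= 1")
  h <- chull(points[, 1], points[, 2])
  hull <- points[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh == 1L)
    return(list(max = 0, min = 0, hull = hull))
  if (nh == 2L) {
    d <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(list(max = d, min = 0, hull = hull))
  }
  fmax <- max(stats::dist(hull))
  # width normal to each edge: project all hull vertices on the edge normal
  nxt <- c(2:nh, 1L)
  ex <- hull[nxt, 1] - hull[, 1]
  ey <- hull[nxt, 2] - hull[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  widths <- vapply(which(keep), function(k) {
    nx <- -ey[k] / len[k]
    ny <- ex[k] / len[k]
    proj <- hull[, 1] * nx + hull[, 2] * ny
    max(proj) - min(proj)
  }, numeric(1))
  list(max = fmax, min = min(widths), hull = hull)
}

#' Area of a simple polygon (shoelace formula)
#'
#' @param xy two-column matrix of vertices in order (open ring).
#' @return area in squared input units.
#' @export
polygon_area <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

# Count pixel centers lying inside (or on) a convex polygon given in physical
# coordinates, for a grid with pixel centers at ((j - 0.5) * s, (i - 0.5) * s).
# Row-wise scanline against the convex hull; exact up to boundary ties, which
# are counted as inside.
count_hull_pixels <- function(hull, pixel_scale) {
  s <- pixel_scale
  ymin <- min(hull[, 2]); ymax <- max(hull[, 2])
  i_lo <- max(1L, as.integer(ceiling(ymin / s + 0.5 - 1e-9)))
  i_hi <- as.integer(floor(ymax / s + 0.5 + 1e-9))
  if (i_hi < i_lo) return(0L)
  nh <- nrow(hull)
  nxt <- c(2:nh, 1L)
  x1 <- hull[, 1]; y1 <- hull[, 2]
  x2 <- hull[nxt, 1]; y2 <- hull[nxt, 2]
  total <- 0L
  for (i in i_lo:i_hi) {
    yc <- (i - 0.5) * s
    cross <- (pmin(y1, y2) - 1e-9 <= yc) & (yc <= pmax(y1, y2) + 1e-9)
    if (!any(cross)) next
    xs <- numeric(0)
    for (k in which(cross)) {
      if (abs(y2[k] - y1[k]) < 1e-12) {
        xs <- c(xs, x1[k], x2[k])
      } else {
        xs <- c(xs, x1[k] + (yc - y1[k]) * (x2[k] - x1[k]) / (y2[k] - y1[k]))
      }
    }
    j_lo <- as.integer(ceiling(min(xs) / s + 0.5 - 1e-9))
    j_hi <- as.integer(floor(max(xs) / s + 0.5 + 1e-9))
    if (j_hi >= j_lo) total <- total + (j_hi - j_lo + 1L)
  }
  total
}
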