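#' Point-in-polygon test (even-odd rule)
#'
#' A pixel belongs to the cell interior iff its center lies inside the
#' manually drawn cell-edge polygon, by the even-odd (ray crossing) rule.
#' Points exactly on an edge are resolved by the crossing parity and should
#' not be relied upon.
#'
#' @param points numeric matrix (n x 2) of (row, col) coordinates.
#' @param polygon numeric matrix (v x 2) of (row, col) vertices in order,
#'   v >= 3; the polygon is closed implicitly.
#' @return Logical vector of length n.
#' @export
point_in_polygon <- function(points, polygon) {
  points <- rbind(points)
  polygon <- check_polygon(polygon)
  py <- points[, 1]; px <- points[, 2]
  v <- nrow(polygon)
  inside <- logical(nrow(points))
  j <- v
  for (i in seq_len(v)) {
    y1 <- polygon[i, 1]; x1 <- polygon[i, 2]
    y2 <- polygon[j, 1]; x2 <- polygon[j, 2]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

check_polygon <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("polygon must be a (>= 3) x 2 matrix of (row, col) vertices")
  storage.mode(polygon) <- "double"
  polygon
}

# Distance from centre `centro` to the polygon boundary along the ray
# through each point: nearest positive intersection with any polygon
# segment, in continuous coordinates. Returns NA where the ray misses the
# boundary entirely (should not happen for points inside the polygon).
ray_edge_distance <- function(points, centro, polygon) {
  points <- rbind(points)
  polygon <- check_polygon(polygon)
  dy <- points[, 1] - centro[1]
  dx <- points[, 2] - centro[2]
  len <- sqrt(dy^2 + dx^2)
  uy <- ifelse(len > 0, dy / len, 0)
  ux <- ifelse(len > 0, dx / len, 0)
  v <- nrow(polygon)
  best <- rep(NA_real_, nrow(points))
  eps <- 1e-9
  j <- v
  for (i in seq_len(v)) {
    ay <- polygon[j, 1]; ax <- polygon[j, 2]
    ey <- polygon[i, 1] - ay; ex <- polygon[i, 2] - ax
    wy <- ay - centro[1]; wx <- ax - centro[2]
    denom <- ux * ey - uy * ex
    tt <- (wx * ey - wy * ex) / denom
    ss <- (wx * uy - wy * ux) / denom
    ok <- is.finite(tt) & abs(denom) > eps &
      ss >= -eps & ss <= 1 + eps & tt > eps
    best <- ifelse(ok & (is.na(best) | tt < best), tt, best)
    j <- i
  }
  best[len == 0] <- NA_real_  # centre itself: no direction, rho is 0 anyway
  best
}

#' Normalized radius of a point within a cell polygon
#'
#' The radial coordinate used by the concentric-belt algorithm: the distance
#' from the centrosome to the point, divided by the distance from the
#' centrosome to the cell edge along the same ray (first boundary
#' intersection). It is 0 at the centrosome and 1 on the drawn edge, so
#' belts of equal radial width follow the cell shape rather than a fixed
#' circle.
#'
#' @param points numeric matrix (n x 2) or length-2 vector of (row, col)
#'   coordinates, assumed inside the polygon.
#' @param centro length-2 (row, col) centrosome coordinate, inside the
#'   polygon.
#' @param polygon cell-edge polygon, (v x 2) matrix of (row, col) vertices.
#' @return Numeric vector of normalized radii in \[0, 1\] (up to
#'   rasterization tolerance at the boundary).
#' @examples
#' sq <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
#' normalized_radius(c(5, 7.5), c(5, 5), sq)  # halfway to the right edge
#' @export
normalized_radius <- function(points, centro, polygon) {
  points <- rbind(points)
  polygon <- check_polygon(polygon)
  dy <- points[, 1] - centro[1]
  dx <- points[, 2] - centro[2]
  len <- sqrt(dy^2 + dx^2)
  R <- ray_edge_distance(points, centro, polygon)
  rho <- unname(ifelse(len == 0, 0, len / R))
  if (any(is.na(rho) & len > 0))
    stop("ray-boundary intersection failed: is the centrosome inside the polygon?")
  rho
}

# logical mask of pixels whose centers fall inside the polygon
polygon_mask <- function(dims, polygon) {
  grid <- cbind(rep(seq_len(dims[1]), dims[2]),
                rep(seq_len(dims[2]), each = dims[1]))
  matrix(point_in_polygon(grid, polygon), dims[1], dims[2])
}
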