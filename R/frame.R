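#' Construct a plane
#' @param point a point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  structure(list(point = as.numeric(point), normal = .unit(as.numeric(normal))),
            class = "plane3")
}

#' Construct a line
#' @param point a point on the line (mm).
#' @param direction line direction (normalized internally).
#' @return An object of class `line3`.
#' @export
line3 <- function(point, direction) {
  structure(list(point = as.numeric(point),
                 direction = .unit(as.numeric(direction))),
            class = "line3")
}

#' Signed distances of points to a plane
#' @param points n x 3 matrix or length-3 vector.
#' @param plane a [plane3].
#' @return numeric vector of signed distances (mm), positive on the normal side.
#' @export
plane_signed_distance <- function(points, plane) {
  p <- if (is.matrix(points)) points else matrix(points, 1)
  as.numeric(sweep(p, 2, plane$point) %*% plane$normal)
}

#' Total-least-squares 3D line fit
#'
#' Fits a line through the centroid along the first principal component of
#' the points.
#'
#' @param points k x 3 matrix, k >= 2.
#' @return A [line3].
#' @export
fit_line_tls <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points to fit a line")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  line3(ctr, sv$v[, 1])
}

#' Intersection of the horizontal and vertical laser traces
#'
#' Each trace is reduced to its total-least-squares 3D line; the origin is
#' the midpoint of the closest-approach segment between the two lines. Traces
#' are required to approximately cross: a closest-approach distance of 2 mm
#' or more (or parallel lines) is an error.
#'
#' @param horizontal the complete (direct) horizontal [laser_trace].
#' @param vertical the vertical [laser_trace].
#' @param tol maximal closest-approach distance in mm (default 2).
#' @return A 3D point (length-3 numeric).
#' @export
laser_origin <- function(horizontal, vertical, tol = 2) {
  l1 <- fit_line_tls(horizontal$points)
  l2 <- fit_line_tls(vertical$points)
  d1 <- l1$direction
  d2 <- l2$direction
  w0 <- l1$point - l2$point
  a <- 1
  b <- sum(d1 * d2)
  denom <- a - b^2
  if (denom < 1e-12)
    stop("laser traces are parallel; cannot construct the origin")
  cc <- sum(d1 * w0)
  dd <- sum(d2 * w0)
  s <- (b * dd - cc) / denom
  t <- (dd - b * cc) / denom
  p1 <- l1$point + s * d1
  p2 <- l2$point + t * d2
  gap <- sqrt(sum((p1 - p2)^2))
  if (gap >= tol)
    stop(sprintf("laser traces do not cross (closest approach %.2f mm >= %.1f mm)",
                 gap, tol))
  (p1 + p2) / 2
}

#' Build the mid-sagittal reference frame from the orthogonal laser traces
#'
#' Implements the laser-based construction on the baseline scan: the origin
#' is the intersection of the horizontal and vertical lasers; the horizontal
#' plane (Plane 1) passes through the origin and the two farthest-apart
#' points of the complete horizontal trace; Line 1 runs through the origin
#' perpendicular to Plane 1 (the vertical axis); Line 2 joins the origin to
#' the vertical-trace point farthest from it; the mid-sagittal plane
#' (Plane 2) is spanned by Line 1 and Line 2 through the origin; and the
#' projection direction (Line 3) is the Plane 2 normal, oriented toward the
#' subject's right (positive dot product with the vector from the first to
#' the last point of the horizontal trace, which is ordered left to right).
#'
#' @param horizontal the complete horizontal [laser_trace], ordered from the
#'   subject's left to the subject's right.
#' @param vertical the vertical [laser_trace].
#' @return An object of class `sagittal_frame` with fields `origin`,
#'   `horizontal_plane`, `midsagittal_plane`, `vertical_axis`,
#'   `projection_direction` and `inplane_axis`.
#' @export
build_frame <- function(horizontal, vertical) {
  if (horizontal$kind != "horizontal-complete")
    stop("the complete horizontal laser must be used to construct the horizontal plane")
  origin <- laser_origin(horizontal, vertical)

  # extremal pair: the two farthest-apart points of the horizontal trace
  hp <- horizontal$points
  dm <- as.matrix(dist(hp))
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  a <- hp[ij[1], ]
  b <- hp[ij[2], ]
  n1 <- .cross3(a - origin, b - origin)
  if (sqrt(sum(n1^2)) < 1e-9)
    stop("degenerate horizontal plane: origin and extremal points are collinear")
  n1 <- .unit(n1)

  vp <- vertical$points
  far <- vp[which.max(.row_norms(sweep(vp, 2, origin))), ]
  l2dir <- far - origin
  sin_ang <- sqrt(sum(.cross3(.unit(l2dir), n1)^2))
  if (sin_ang < sin(0.1 * pi / 180))
    stop("degenerate frame: Line 2 is parallel to Line 1 within 0.1 degree")
  if (abs(sum(.unit(l2dir) * n1)) < sin(0.1 * pi / 180))
    stop("degenerate frame: vertical trace lies in the horizontal plane")

  # sign conventions: the vertical axis points superiorly (vertical trace is
  # ordered inferior to superior), the projection direction points toward the
  # subject's right (horizontal trace is ordered left to right)
  if (sum(n1 * (vp[nrow(vp), ] - vp[1, ])) < 0) n1 <- -n1
  n2 <- .unit(.cross3(n1, l2dir))          # Plane 2 normal = Line 3
  lr <- hp[nrow(hp), ] - hp[1, ]           # left -> right chord
  if (sum(n2 * lr) < 0) n2 <- -n2
  inpl <- .unit(.cross3(n1, n2))

  structure(list(origin = origin,
                 horizontal_plane = plane3(origin, n1),
                 midsagittal_plane = plane3(origin, n2),
                 vertical_axis = n1,
                 projection_direction = n2,
                 inplane_axis = inpl),
            class = "sagittal_frame")
}

#' @export
print.sagittal_frame <- function(x, ...) {
  cat(sprintf("sagittal_frame: origin (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  projection direction (%.4f, %.4f, %.4f)\n",
              x$projection_direction[1], x$projection_direction[2],
              x$projection_direction[3]))
  invisible(x)
}

#' Frame coordinates of points
#'
#' Decomposes points relative to the frame origin into `s` (along the
#' projection direction, i.e. signed distance to the mid-sagittal plane),
#' `u` (along the vertical axis) and `v` (along the in-plane axis).
#'
#' @param points n x 3 matrix.
#' @param frame a [sagittal_frame].
#' @return n x 3 matrix with columns `s`, `u`, `v`.
#' @export
frame_coords <- function(points, frame) {
  p <- sweep(as.matrix(points), 2, frame$origin)
  out <- cbind(s = as.numeric(p %*% frame$projection_direction),
               u = as.numeric(p %*% frame$vertical_axis),
               v = as.numeric(p %*% frame$inplane_axis))
  out
}

#' Serialize a sagittal frame to JSON
#' @param frame a [sagittal_frame].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_frame_json <- function(frame, path) {
  jsonlite::write_json(
    list(origin = frame$origin,
         horizontal_plane = list(point = frame$horizontal_plane$point,
                                 normal = frame$horizontal_plane$normal),
         midsagittal_plane = list(point = frame$midsagittal_plane$point,
                                  normal = frame$midsagittal_plane$normal),
         vertical_axis = frame$vertical_axis,
         projection_direction = frame$projection_direction,
         inplane_axis = frame$inplane_axis),
    path, digits = NA)
  invisible(path)
}
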