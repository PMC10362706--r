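#' Construct a rigid transform
#'
#' A rotation (proper orthonormal 3 x 3 matrix, determinant +1) followed by a
#' translation in mm: `p -> R p + t`.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (length(translation) != 3L) stop("translation must be length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation matrix from axis and angle
#' @param axis rotation axis (any length, normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- .unit(as.numeric(axis))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3 x 3 rotation matrix.
#' @return angle in degrees, in [0, 180].
#' @export
rotation_angle_deg <- function(R) {
  c0 <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c0))) * 180 / pi
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform]s.
#' @return A [rigid_transform].
#' @export
compose_transform <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Invert a rigid transform
#' @param t a [rigid_transform].
#' @return A [rigid_transform] undoing `t`.
#' @export
invert_transform <- function(t) {
  Ri <- t(t$rotation)
  rigid_transform(Ri, -as.numeric(Ri %*% t$translation))
}

#' Apply a rigid transform to points or to a scan
#'
#' Every vertex is mapped by the rotation then the translation; mesh topology
#' is unchanged.
#'
#' @param x a [surface_scan], [laser_trace], or an n x 3 point matrix.
#' @param t a [rigid_transform].
#' @return The transformed object, same class as `x`.
#' @export
apply_transform <- function(x, t) {
  map <- function(p) sweep(p %*% t(t$rotation), 2, t$translation, "+")
  if (inherits(x, "surface_scan")) {
    x$vertices <- map(x$vertices)
    x
  } else if (inherits(x, "laser_trace")) {
    x$points <- map(x$points)
    x
  } else {
    map(as.matrix(x))
  }
}

#' Serialize a rigid transform to a 4 x 4 homogeneous-matrix JSON file
#' @param t a [rigid_transform].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(t, path) {
  H <- rbind(cbind(t$rotation, t$translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = H), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a rigid transform from a 4 x 4 homogeneous-matrix JSON file
#' @param path JSON path written by [write_transform_json()].
#' @return A [rigid_transform].
#' @export
read_transform_json <- function(path) {
  H <- jsonlite::fromJSON(path)$matrix
  rigid_transform(H[1:3, 1:3], H[1:3, 4])
}
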