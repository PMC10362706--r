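#' 3D-compare deviation analysis between two registered patches
#'
#' For every reference vertex, the signed closest-point distance `Xi` to the
#' test surface is computed; the sign is positive when the test surface lies
#' outside the reference along its outward vertex normal. Correspondences
#' farther than `max_dist` are excluded. Summaries use the population
#' formulas: `mu = mean(Xi)`, `SD = sqrt(mean((Xi - mu)^2))`,
#' `RMS = sqrt(mean(Xi^2))`, so `RMS^2 = mu^2 + SD^2` identically.
#'
#' @param reference a [buccal_patch] or [surface_scan] (reference surface).
#' @param test a [buccal_patch] or [surface_scan] (test surface), registered
#'   in the same frame.
#' @param max_dist correspondences with |Xi| above this are discarded
#'   (default 10 mm, matching the ring sweep half-length).
#' @return An object of class `deviation_result` with fields `distances`,
#'   `mu`, `sd`, `rms`, `n`.
#' @export
compare_surfaces <- function(reference, test, max_dist = 10) {
  rv <- reference$vertices
  rn <- .vertex_normals(reference$vertices, reference$faces)
  cp <- cpp_closest_point_mesh(test$vertices, test$faces - 1L, rv)
  delta <- cp$point - rv
  sgn <- ifelse(rowSums(delta * rn) >= 0, 1, -1)
  x <- sgn * cp$dist
  x <- x[abs(x) <= max_dist]
  if (length(x) == 0L)
    stop("zero correspondences within max_dist = ", max_dist, " mm")
  deviation_result(x)
}

#' Summarize signed distances with the population mu/SD/RMS formulas
#'
#' @param distances numeric vector of signed distances Xi (mm).
#' @return A `deviation_result`.
#' @export
deviation_result <- function(distances) {
  x <- as.numeric(distances)
  if (length(x) == 0L) stop("zero correspondences")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))   # population (1/N) formula
  rms <- sqrt(mean(x^2))
  structure(list(distances = x, mu = mu, sd = sdev, rms = rms,
                 n = length(x)),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("deviation: n = %d, mu = %.4f mm, SD = %.4f mm, RMS = %.4f mm\n",
              x$n, x$mu, x$sd, x$rms))
  invisible(x)
}

#' Export per-vertex deviation distances as CSV
#' @param result a [deviation_result].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_deviation_csv <- function(result, path) {
  write.csv(data.frame(distance_mm = result$distances), path,
            row.names = FALSE)
  invisible(path)
}
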