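#' Construct and validate a surface scan
#'
#' A `surface_scan` is a triangle mesh in millimetres: an `n x 3` vertex
#' matrix and an `m x 3` integer face matrix (1-based vertex indices), plus a
#' time-point label such as `"T0"`. Validation enforces finite coordinates,
#' in-range face indices, and removes degenerate (zero-area) triangles.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param label time-point tag, e.g. "T0".
#' @return An object of class `surface_scan`.
#' @export
surface_scan <- function(vertices, faces, label = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(vertices) == 0L) stop("empty mesh: no vertices")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(faces) == 0L) stop("empty mesh: no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face references an out-of-range vertex index")
  areas <- .row_norms(.face_vector_areas(vertices, faces))
  degen <- areas <= 1e-12
  if (any(degen)) faces <- faces[!degen, , drop = FALSE]
  if (nrow(faces) == 0L) stop("empty mesh: all faces degenerate")
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "surface_scan")
}

#' @export
print.surface_scan <- function(x, ...) {
  cat(sprintf("surface_scan '%s': %d vertices, %d faces\n",
              x$label, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a Wavefront OBJ file as a surface scan
#'
#' Only `v` and `f` records are interpreted; texture/normal indices inside
#' `f` records are ignored. Faces with more than three vertices are
#' triangulated deterministically as a fan from the first vertex, so vertex
#' count is unchanged.
#'
#' @param path path to an ASCII OBJ file.
#' @param label time-point tag stored on the scan.
#' @return A [surface_scan].
#' @export
read_obj <- function(path, label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  key <- vapply(toks, function(t) if (length(t)) t[[1]] else "", "")
  vidx <- which(key == "v")
  fidx <- which(key == "f")
  if (length(vidx) == 0L) stop("empty mesh: no 'v' records in ", path)
  verts <- matrix(NA_real_, length(vidx), 3)
  for (i in seq_along(vidx)) {
    t <- toks[[vidx[i]]]
    if (length(t) < 4L)
      stop(sprintf("malformed OBJ vertex at line %d of %s", vidx[i], path))
    v <- suppressWarnings(as.numeric(t[2:4]))
    if (any(is.na(v)))
      stop(sprintf("malformed OBJ vertex at line %d of %s", vidx[i], path))
    verts[i, ] <- v
  }
  if (length(fidx) == 0L) stop("empty mesh: no 'f' records in ", path)
  tris <- vector("list", length(fidx))
  for (i in seq_along(fidx)) {
    t <- toks[[fidx[i]]][-1]
    if (length(t) < 3L)
      stop(sprintf("malformed OBJ face at line %d of %s", fidx[i], path))
    ix <- suppressWarnings(as.integer(sub("/.*$", "", t)))
    if (any(is.na(ix)))
      stop(sprintf("malformed OBJ face at line %d of %s", fidx[i], path))
    neg <- !is.na(ix) & ix < 0L
    ix[neg] <- nrow(verts) + 1L + ix[neg]
    # fan triangulation from the first vertex
    k <- length(ix)
    tris[[i]] <- cbind(ix[1], ix[2:(k - 1)], ix[3:k])
  }
  surface_scan(verts, do.call(rbind, tris), label = label)
}

#' Write a surface scan to a Wavefront OBJ file
#'
#' Coordinates are written with enough digits to round-trip within 1e-6 mm.
#'
#' @param scan a [surface_scan].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(scan, path) {
  v <- sprintf("v %.9f %.9f %.9f",
               scan$vertices[, 1], scan$vertices[, 2], scan$vertices[, 3])
  f <- sprintf("f %d %d %d",
               scan$faces[, 1], scan$faces[, 2], scan$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

#' Construct a laser trace
#'
#' An ordered 3D polyline recorded from a laser line projected on the face.
#' The `horizontal-complete` trace (the direct, unreflected projection
#' crossing the middle of the face) is the one used to construct the
#' horizontal plane; the two mirror-reflected partial lines are labelled
#' `horizontal-reflected`.
#'
#' @param points numeric matrix, k x 3, ordered points in mm. A horizontal
#'   trace is ordered from the subject's left to the subject's right; a
#'   vertical trace from inferior to superior. These orderings fix the sign
#'   conventions of [build_frame()].
#' @param kind one of "horizontal-complete", "horizontal-reflected",
#'   "vertical".
#' @return An object of class `laser_trace`.
#' @export
laser_trace <- function(points,
                        kind = c("horizontal-complete",
                                 "horizontal-reflected", "vertical")) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stop("laser trace points must be k x 3")
  if (nrow(points) < 2L) stop("laser trace needs at least 2 points")
  if (!all(is.finite(points))) stop("non-finite laser trace coordinates")
  structure(list(points = points, kind = kind), class = "laser_trace")
}

#' Read a laser trace from an OBJ polyline
#'
#' Reads the `v` records of an OBJ file, in file order, as an ordered
#' polyline (`l` records, if present, are ignored for ordering).
#'
#' @inheritParams laser_trace
#' @param path path to an OBJ file holding the trace vertices.
#' @return A [laser_trace].
#' @export
read_laser_obj <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "[ \t]+")
  key <- vapply(toks, function(t) if (length(t)) t[[1]] else "", "")
  vidx <- which(key == "v")
  if (length(vidx) < 2L) stop("laser OBJ has fewer than 2 vertices: ", path)
  pts <- t(vapply(toks[vidx], function(t) as.numeric(t[2:4]), numeric(3)))
  laser_trace(pts, kind = kind)
}

#' Write a laser trace as an OBJ polyline
#' @param trace a [laser_trace].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_laser_obj <- function(trace, path) {
  p <- trace$points
  v <- sprintf("v %.9f %.9f %.9f", p[, 1], p[, 2], p[, 3])
  l <- paste("l", paste(seq_len(nrow(p)), collapse = " "))
  writeLines(c(v, l), path)
  invisible(path)
}

.landmark_codes <- c("pt'", "al'", "ex'", "ch'", "cf'")

#' Construct a landmark set
#'
#' Named anthropometric soft-tissue landmarks (primed codes) plus an ordered
#' list of points along the lower border of the mandible. Recognized codes:
#' pt' (posterotragion), al' (alare), ex' (exocanthion), ch' (cheilion),
#' cf' (chin footpoint, usually derived via [chin_footpoint()] rather than
#' supplied), and "mb" for mandible-border points (order preserved).
#'
#' @param points named list (or 3-column matrix with rownames) of landmark
#'   coordinates in mm, one entry per primed code.
#' @param mandible_border ordered k x 3 matrix of mandible lower-border
#'   points.
#' @param side which side of the face the set describes.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, mandible_border = NULL,
                         side = c("right", "left")) {
  side <- match.arg(side)
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) as.numeric(points[i, ]))
    names(points) <- nm
  }
  nm <- names(points)
  if (is.null(nm) || any(nm == "")) stop("landmarks must be named")
  bad <- setdiff(nm, .landmark_codes)
  if (length(bad))
    stop("unknown landmark code(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(nm))
    stop("duplicated landmark code(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  points <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3L || !all(is.finite(p)))
      stop("each landmark must be a finite 3D point")
    p
  })
  if (!is.null(mandible_border)) {
    mandible_border <- as.matrix(mandible_border)
    storage.mode(mandible_border) <- "double"
    if (ncol(mandible_border) != 3L)
      stop("mandible border must be a k x 3 matrix")
  }
  structure(list(points = points, mandible_border = mandible_border,
                 side = side),
            class = "landmark_set")
}

#' Read landmarks from CSV and validate against a scan
#'
#' File format: plain CSV lines `code,x,y,z` (no header), coordinates in mm.
#' The code `mb` may repeat; its rows form the ordered mandible lower-border
#' list. Points farther than `tolerance` from the scan surface trigger a
#' warning (recorded, not fatal); unknown codes are an error.
#'
#' @param path CSV file path.
#' @param scan [surface_scan] the landmarks were digitized on, or `NULL` to
#'   skip the surface-distance check.
#' @param tolerance landmark-to-surface tolerance in mm (default 1.0).
#' @param side face side tag.
#' @return A [landmark_set]; off-surface warnings are attached as the
#'   `"off_surface"` attribute.
#' @export
read_landmarks <- function(path, scan = NULL, tolerance = 1.0,
                           side = c("right", "left")) {
  side <- match.arg(side)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                 col.names = c("code", "x", "y", "z"))
  df$code <- trimws(df$code)
  bad <- setdiff(unique(df$code), c(.landmark_codes, "mb"))
  if (length(bad))
    stop("unknown landmark code(s): ", paste(bad, collapse = ", "))
  mb <- as.matrix(df[df$code == "mb", c("x", "y", "z")])
  named <- df[df$code != "mb", , drop = FALSE]
  pts <- lapply(seq_len(nrow(named)), function(i) as.numeric(named[i, 2:4]))
  names(pts) <- named$code
  lm <- landmark_set(pts, mandible_border = if (nrow(mb)) mb else NULL,
                     side = side)
  if (!is.null(scan)) {
    all_pts <- rbind(do.call(rbind, lm$points), lm$mandible_border)
    cp <- cpp_closest_point_mesh(scan$vertices, scan$faces - 1L, all_pts)
    off <- which(cp$dist > tolerance)
    if (length(off)) {
      codes <- c(names(lm$points), rep("mb", NROW(lm$mandible_border)))
      msg <- sprintf("%s (%.2f mm)", codes[off], cp$dist[off])
      warning("landmark(s) off surface beyond ", tolerance, " mm: ",
              paste(msg, collapse = "; "))
      attr(lm, "off_surface") <- data.frame(code = codes[off],
                                            dist = cp$dist[off])
    }
  }
  lm
}

#' Write a landmark set to CSV
#' @param landmarks a [landmark_set].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  rows <- c(
    vapply(names(landmarks$points), function(code) {
      p <- landmarks$points[[code]]
      sprintf("%s,%.9f,%.9f,%.9f", code, p[1], p[2], p[3])
    }, ""),
    if (!is.null(landmarks$mandible_border))
      sprintf("mb,%.9f,%.9f,%.9f",
              landmarks$mandible_border[, 1],
              landmarks$mandible_border[, 2],
              landmarks$mandible_border[, 3]))
  writeLines(rows, path)
  invisible(path)
}
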