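#' Extrude the buccal boundary into a ring model
#'
#' Sweeps the baseline (T0) buccal boundary loop from `-half_length` to
#' `+half_length` along the projection direction (the mid-sagittal normal,
#' Line 3), producing an open band with exactly two parallel boundary loops
#' and none of the original patch interior: the "ring model" used to transfer
#' the T0 boundary onto later scans.
#'
#' @param patch the baseline [buccal_patch] (closed boundary loop required).
#' @param direction unit 3-vector, the projection direction.
#' @param half_length sweep half-length in mm (default 10, matching the
#'   boundary-transfer protocol).
#' @return An object of class `ring_model`: fields `vertices`, `faces`
#'   (the swept band), `loop` (the ordered T0 boundary loop coordinates),
#'   `direction`, `half_length`; attribute `self_intersecting` flags a
#'   non-simple projected loop.
#' @export
extrude_ring <- function(patch, direction, half_length = 10) {
  if (half_length <= 0) stop("half_length must be positive (degenerate ring)")
  d <- .unit(as.numeric(direction))
  loop <- patch$vertices[patch$boundary, , drop = FALSE]
  n <- nrow(loop)
  if (n < 3L) stop("patch boundary is not a closed loop")
  lo <- sweep(loop, 2, half_length * d)
  hi <- sweep(loop, 2, half_length * d, "+")
  verts <- rbind(lo, hi)
  nxt <- c(2:n, 1L)
  faces <- rbind(cbind(seq_len(n), nxt, n + nxt),
                 cbind(seq_len(n), n + nxt, n + seq_len(n)))
  # simplicity check of the projected loop (warn only; the cut may still fail)
  basis <- .orthobasis(d)
  uv <- sweep(loop, 2, colMeans(loop)) %*% basis
  selfx <- .polygon_self_intersects(uv)
  if (selfx)
    warning("projected boundary loop self-intersects; downstream cut may fail")
  structure(list(vertices = verts, faces = faces, loop = loop,
                 direction = d, half_length = half_length,
                 side = patch$side),
            class = "ring_model",
            self_intersecting = selfx)
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf("ring_model: %d boundary vertices, half-length %.1f mm\n",
              nrow(x$loop), x$half_length))
  invisible(x)
}

.orthobasis <- function(d) {
  # two unit vectors orthogonal to d (columns)
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross3(d, a))
  v <- .cross3(d, u)
  cbind(u, v)
}

.polygon_self_intersects <- function(uv) {
  n <- nrow(uv)
  if (n > 2000L) {
    # subsample for the check; fine for a warning-level diagnostic
    uv <- uv[unique(round(seq(1, n, length.out = 2000L))), , drop = FALSE]
    n <- nrow(uv)
  }
  p1 <- uv
  p2 <- uv[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    j <- seq(i + 2L, n)
    j <- j[!(i == 1L & j == n)]
    if (!length(j)) next
    d1 <- p2[i, ] - p1[i, ]
    o1 <- (p1[j, 1] - p1[i, 1]) * d1[2] - (p1[j, 2] - p1[i, 2]) * d1[1]
    o2 <- (p2[j, 1] - p1[i, 1]) * d1[2] - (p2[j, 2] - p1[i, 2]) * d1[1]
    dj <- p2[j, , drop = FALSE] - p1[j, , drop = FALSE]
    o3 <- (p1[i, 1] - p1[j, 1]) * dj[, 2] - (p1[i, 2] - p1[j, 2]) * dj[, 1]
    o4 <- (p2[i, 1] - p1[j, 1]) * dj[, 2] - (p2[i, 2] - p1[j, 2]) * dj[, 1]
    if (any(o1 * o2 < 0 & o3 * o4 < 0)) return(TRUE)
  }
  FALSE
}

#' Cut a registered scan with the ring model
#'
#' Transfers the baseline buccal boundary onto a later scan: the scan
#' (already registered into the baseline frame) is cut along the swept band
#' of the ring model. Faces are classified by projecting their centroids
#' along the sweep direction and testing them against the projected T0
#' boundary polygon; the enclosed connected component is returned as the
#' later time point's buccal patch. This is the open-surface equivalent of
#' the Boolean subtraction between the ring model and the scan.
#'
#' @param ring a [ring_model] built from the baseline patch.
#' @param scan a registered [surface_scan].
#' @return A [buccal_patch] on `scan` with the cut curve as boundary.
#' @export
boolean_cut <- function(ring, scan) {
  d <- ring$direction
  basis <- .orthobasis(d)
  ctr <- colMeans(ring$loop)
  loop_uv <- sweep(ring$loop, 2, ctr) %*% basis
  loop_s <- as.numeric(sweep(ring$loop, 2, ctr) %*% d)

  # does the ring intersect the scan? probe the scan surface height (along d)
  # near each loop vertex
  vuv <- sweep(scan$vertices, 2, ctr) %*% basis
  vs <- as.numeric(sweep(scan$vertices, 2, ctr) %*% d)
  nprobe <- min(nrow(ring$loop), 64L)
  probe <- unique(round(seq(1, nrow(ring$loop), length.out = nprobe)))
  hit <- vapply(probe, function(i) {
    d2 <- (vuv[, 1] - loop_uv[i, 1])^2 + (vuv[, 2] - loop_uv[i, 2])^2
    j <- which.min(d2)
    abs(vs[j] - loop_s[i]) <= ring$half_length
  }, logical(1))
  if (!any(hit))
    stop("ring model does not intersect the scan (surface beyond the swept band)")

  cen <- .face_centroids(scan$vertices, scan$faces)
  cuv <- sweep(cen, 2, ctr) %*% basis
  inside <- cpp_point_in_polygon(loop_uv, cuv)
  if (!any(inside))
    stop("ring model does not intersect the scan (no faces project inside the loop)")

  # all enclosed surface must lie within the swept band
  iv <- unique(as.integer(scan$faces[inside, ]))
  band_lo <- min(loop_s) - ring$half_length
  band_hi <- max(loop_s) + ring$half_length
  if (any(vs[iv] < band_lo | vs[iv] > band_hi))
    stop("scan points inside the boundary loop lie beyond the swept band; ",
         "increase half_length or check registration")

  # connected component(s) of the enclosed faces
  sel <- which(inside)
  fsel <- scan$faces[sel, , drop = FALSE]
  memb <- .face_adjacency_components(fsel, matrix(integer(0), 0, 2))
  ids <- sort(unique(memb))
  if (length(ids) > 1L) {
    areas <- vapply(ids, function(cid)
      sum(.row_norms(.face_vector_areas(scan$vertices,
                                        fsel[memb == cid, , drop = FALSE]))),
      numeric(1))
    big <- which.max(areas)
    if (max(areas[-big]) > 0.01 * areas[big])
      stop("ambiguous cut: multiple intersection components; areas (mm^2): ",
           paste(sprintf("%.1f", areas), collapse = ", "))
    sel <- sel[memb == ids[big]]
    fsel <- scan$faces[sel, , drop = FALSE]
  }

  sub <- .submesh(scan, sel)
  bl <- .order_boundary_loop(sub$faces)
  out <- buccal_patch(sub$vertices, sub$faces, bl, side = ring$side,
                      label = scan$label)
  attr(out, "parent_vertices") <- sub$parent_vertices
  out
}

.order_boundary_loop <- function(faces) {
  open <- .open_edges(faces)
  if (nrow(open) < 3L) stop("cut patch has no boundary loop")
  adj <- split(c(open[, 2], open[, 1]), c(open[, 1], open[, 2]))
  start <- open[1, 1]
  loop <- c(start)
  prev <- -1L
  cur <- start
  repeat {
    nbrs <- adj[[as.character(cur)]]
    nxt <- nbrs[nbrs != prev][1]
    if (is.na(nxt)) break
    if (nxt == start) break
    loop <- c(loop, nxt)
    prev <- cur
    cur <- nxt
    if (length(loop) > nrow(open) + 1L) break
  }
  loop
}

#' Projected soft-tissue volume of a buccal patch
#'
#' STV is the volume of the solid between the patch and its orthogonal
#' projection onto the mid-sagittal plane, computed as the sum over triangles
#' of the signed distance of the centroid to the plane times the triangle's
#' area projected onto the plane (signed prism summation). The patch must lie
#' on one side of the plane; faces of opposite sign up to 0.1% of the patch
#' area are clipped (dropped), more is an error.
#'
#' @param patch a [buccal_patch].
#' @param frame a [sagittal_frame]; its mid-sagittal plane and projection
#'   direction define the measurement.
#' @return An object of class `volume_result`: `stv` in ml (1 ml = 1000
#'   mm^3, positive for a patch on its anatomical side), `side`, `timepoint`,
#'   `area` (patch area, mm^2), `projected_area` (mm^2).
#' @export
stv <- function(patch, frame) {
  n <- frame$midsagittal_plane$normal
  cen <- .face_centroids(patch$vertices, patch$faces)
  s <- plane_signed_distance(cen, frame$midsagittal_plane)
  va <- .face_vector_areas(patch$vertices, patch$faces)
  area <- .row_norms(va)
  aproj <- abs(as.numeric(va %*% n))
  # |s| below float fuzz counts as on-plane, not wrong-sided
  wrong <- if (patch$side == "left") s > 1e-9 else s < -1e-9
  if (any(wrong)) {
    if (sum(area[wrong]) > 1e-3 * sum(area))
      stop(sprintf(
        "patch crosses the mid-sagittal plane (%.2f%% of area on the wrong side)",
        100 * sum(area[wrong]) / sum(area)))
    s[wrong] <- 0
  }
  vol <- sum(abs(s) * aproj)
  structure(list(stv = vol / 1000, side = patch$side,
                 timepoint = patch$label, area = sum(area),
                 projected_area = sum(aproj)),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("STV %s %s: %.4f ml (patch area %.1f mm^2)\n",
              x$side, x$timepoint, x$stv, x$area))
  invisible(x)
}

#' Soft-tissue volume change between two time points
#'
#' @param earlier,later [volume_result]s for the same side and frame.
#' @return numeric STVC in ml (later minus earlier), with attribute
#'   `"period"` like "T1-T0".
#' @export
stvc <- function(earlier, later) {
  if (earlier$side != later$side)
    stop("side mismatch: ", earlier$side, " vs ", later$side)
  out <- later$stv - earlier$stv
  attr(out, "period") <- paste0(later$timepoint, "-", earlier$timepoint)
  out
}
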