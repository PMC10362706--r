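#' Crop the upper third of a scan
#'
#' Selects the sub-mesh of vertices whose height coordinate (along the
#' frame's vertical axis) exceeds the `1 - upper_fraction` point of the
#' scan's height range, keeping faces with all three vertices retained. This
#' is the registration region: the upper part of the face is unaffected by
#' buccal soft-tissue change.
#'
#' @param scan a [surface_scan].
#' @param frame a [sagittal_frame] defined on the fixed (baseline) scan.
#' @param upper_fraction fraction of the height range to keep (default 1/3).
#' @return A [surface_scan] sub-mesh; vertex indices into the parent scan are
#'   attached as attribute `"parent_vertices"`.
#' @export
crop_upper_third <- function(scan, frame, upper_fraction = 1 / 3) {
  if (!(upper_fraction > 0 && upper_fraction < 1))
    stop("upper_fraction must be in (0, 1)")
  h <- as.numeric(sweep(scan$vertices, 2, frame$origin) %*% frame$vertical_axis)
  cut <- min(h) + (1 - upper_fraction) * (max(h) - min(h))
  keep <- h > cut
  fkeep <- keep[scan$faces[, 1]] & keep[scan$faces[, 2]] & keep[scan$faces[, 3]]
  if (!any(fkeep)) stop("empty crop: no faces in the upper region")
  used <- sort(unique(as.integer(scan$faces[fkeep, ])))
  remap <- integer(nrow(scan$vertices))
  remap[used] <- seq_along(used)
  out <- surface_scan(scan$vertices[used, , drop = FALSE],
                      matrix(remap[scan$faces[fkeep, ]], ncol = 3),
                      label = scan$label)
  attr(out, "parent_vertices") <- used
  out
}

.edge_keys <- function(e, base) {
  pmin(e[, 1], e[, 2]) * base + pmax(e[, 1], e[, 2])
}

.boundary_faces <- function(faces) {
  # faces having at least one edge not shared with another face
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  base <- max(faces) + 1
  key <- .edge_keys(e, base)
  tab <- sort(key)
  singles <- tab[c(diff(tab) != 0, TRUE) & c(TRUE, diff(tab) != 0)]
  fid <- rep(seq_len(nrow(faces)), 3L)
  unique(fid[key %in% singles])
}

#' Rigid registration by point-to-plane iterative closest point
#'
#' Registers a floating scan to a fixed region (typically the upper third of
#' the baseline face) with point-to-plane ICP: uniformly subsampled floating
#' vertices are matched to their closest points on the fixed surface, matches
#' landing on boundary triangles of the fixed region or farther than three
#' times the median match distance are rejected, and the linearized
#' point-to-plane system is solved each iteration. Iterations stop when the
#' RMS point-to-plane residual improves by less than `tol` or after
#' `max_iter` iterations.
#'
#' @param floating [surface_scan] to be moved.
#' @param fixed_region [surface_scan] target region (kept fixed).
#' @param max_iter maximal number of iterations (default 100).
#' @param tol RMS improvement threshold in mm (default 1e-4).
#' @param n_samples number of floating vertices sampled (default 5000;
#'   deterministic, evenly spaced in vertex order).
#' @param init optional initial [rigid_transform] (default identity).
#' @param min_iter iterations to run before the improvement-based stop may
#'   fire (default 10); guards against plateaus early in a large initial
#'   misalignment.
#' @return A [rigid_transform] mapping floating into the fixed frame, with
#'   attributes `converged` (logical), `iterations` and `rms` (mm).
#' @export
icp_register <- function(floating, fixed_region, max_iter = 100, tol = 1e-4,
                         n_samples = 5000, init = NULL, min_iter = 10) {
  if (nrow(floating$vertices) == 0L || nrow(fixed_region$vertices) == 0L)
    stop("both meshes must be non-empty")
  # samples are drawn from the floating vertices that start inside the fixed
  # region's bounding box (with a margin covering the expected initial
  # misalignment): the same crop region selects both sides' points
  vinit <- if (is.null(init)) floating$vertices else
    apply_transform(floating$vertices, init)
  lo0 <- apply(fixed_region$vertices, 2, min) - 25
  hi0 <- apply(fixed_region$vertices, 2, max) + 25
  cand <- which(vinit[, 1] >= lo0[1] & vinit[, 1] <= hi0[1] &
                vinit[, 2] >= lo0[2] & vinit[, 2] <= hi0[2] &
                vinit[, 3] >= lo0[3] & vinit[, 3] <= hi0[3])
  if (length(cand) < 100L) cand <- seq_len(nrow(floating$vertices))
  idx <- if (length(cand) > n_samples)
    cand[unique(round(seq(1, length(cand), length.out = n_samples)))] else cand
  P0 <- floating$vertices[idx, , drop = FALSE]

  Ffix0 <- fixed_region$faces - 1L
  bf <- .boundary_faces(fixed_region$faces)
  is_boundary <- logical(nrow(fixed_region$faces))
  is_boundary[bf] <- TRUE
  fnorm <- .face_vector_areas(fixed_region$vertices, fixed_region$faces)
  fnorm <- fnorm / .row_norms(fnorm)

  # floating samples far outside the fixed region cannot produce valid
  # correspondences; gate them by the fixed-region bounding box with a margin
  # generous enough for the expected initial misalignment
  bb_lo <- apply(fixed_region$vertices, 2, min) - 25
  bb_hi <- apply(fixed_region$vertices, 2, max) + 25

  tr <- if (is.null(init)) rigid_transform() else init
  rms_prev <- Inf
  converged <- FALSE
  it <- 0L
  rms <- NA_real_
  while (it < max_iter) {
    it <- it + 1L
    P <- apply_transform(P0, tr)
    inbb <- P[, 1] >= bb_lo[1] & P[, 1] <= bb_hi[1] &
            P[, 2] >= bb_lo[2] & P[, 2] <= bb_hi[2] &
            P[, 3] >= bb_lo[3] & P[, 3] <= bb_hi[3]
    if (sum(inbb) >= 100L) P <- P[inbb, , drop = FALSE]
    cp <- cpp_closest_point_mesh(fixed_region$vertices, Ffix0, P)
    ok <- !is_boundary[cp$face]
    if (sum(ok) >= 12L) {
      cap <- 3 * median(cp$dist[ok])
      ok <- ok & cp$dist <= max(cap, 1e-9)
    }
    if (sum(ok) < 12L)
      stop("too few valid correspondences; meshes do not overlap")
    p <- P[ok, , drop = FALSE]
    q <- cp$point[ok, , drop = FALSE]
    n <- fnorm[cp$face[ok], , drop = FALSE]
    r <- rowSums((p - q) * n)
    rms <- sqrt(mean(r^2))
    # a large initial offset can plateau the residual for an iteration or
    # two while the surfaces slide; only trust the improvement-based stop
    # after a minimum number of iterations
    if (rms_prev - rms < tol && it > min_iter) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    cxn <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
                 p[, 3] * n[, 1] - p[, 1] * n[, 3],
                 p[, 1] * n[, 2] - p[, 2] * n[, 1])
    A <- cbind(cxn, n)
    x <- tryCatch(solve(crossprod(A), -crossprod(A, r)),
                  error = function(e) rep(0, 6))
    w <- x[1:3]
    dt <- x[4:6]
    th <- sqrt(sum(w^2))
    Rinc <- if (th < 1e-14) diag(3) else rotation_about_axis(w, th * 180 / pi)
    tr <- rigid_transform(Rinc %*% tr$rotation,
                          as.numeric(Rinc %*% tr$translation) + dt)
  }
  attr(tr, "converged") <- converged
  attr(tr, "iterations") <- it
  attr(tr, "rms") <- rms
  tr
}
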