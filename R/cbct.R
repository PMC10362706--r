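#' Construct a voxel volume
#'
#' A 3D intensity grid with anisotropic spacing in mm. `data[i, j, k]` holds
#' the intensity of the voxel whose center sits at
#' `origin + orientation %*% ((c(i, j, k) - 1) * spacing)`.
#'
#' @param data 3D numeric array.
#' @param spacing length-3 voxel spacing (dx, dy, dz) in mm/voxel.
#' @param origin world coordinates (mm) of the center of voxel (1,1,1).
#' @param orientation 3 x 3 direction matrix (columns = axis directions).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing, origin = c(0, 0, 0),
                         orientation = diag(3)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) == 0L)) stop("empty volume grid")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm/voxel)")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin),
                 orientation = as.matrix(orientation)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume: %d x %d x %d, spacing (%.3f, %.3f, %.3f) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' World coordinates of all voxel centers
#' @param vol a [voxel_volume] or [roi_mask].
#' @return n x 3 matrix (mm), voxels in array order.
#' @export
voxel_centers <- function(vol) {
  d <- if (!is.null(vol$data)) dim(vol$data) else dim(vol$mask)
  ijk <- cbind(rep(seq_len(d[1]) - 1L, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
  sweep(ijk %*% diag(vol$spacing) %*% t(vol$orientation), 2, vol$origin, "+")
}

#' Threshold segmentation of a voxel volume
#'
#' Marks voxels whose intensity falls in the inclusive window
#' `[lower, upper]`, the dual-jaw bone/teeth segmentation step. The window
#' bounds are per-case parameters; the protocol range is a lower bound
#' within 400-700 and an upper bound within 2000-4600 (defaults 550 and
#' 3300, the midpoints). No morphological post-processing is applied.
#'
#' @param vol a [voxel_volume].
#' @param lower,upper inclusive intensity window bounds, `lower < upper`.
#' @param jaw jaw tag carried on the mask ("maxilla" or "mandible").
#' @return An object of class `roi_mask`; an empty mask sets the attribute
#'   `"empty"` to `TRUE` with a warning.
#' @export
threshold_segment <- function(vol, lower = 550, upper = 3300,
                              jaw = "maxilla") {
  if (!(lower < upper)) stop("lower must be < upper")
  m <- vol$data >= lower & vol$data <= upper
  out <- structure(list(mask = m, spacing = vol$spacing,
                        origin = vol$origin, orientation = vol$orientation,
                        jaw = jaw),
                   class = "roi_mask", empty = FALSE)
  if (!any(m)) {
    warning("threshold window [", lower, ", ", upper,
            "] selects no voxels (empty mask)")
    attr(out, "empty") <- TRUE
  }
  out
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask (%s): %d of %d voxels set\n",
              x$jaw, sum(x$mask), length(x$mask)))
  invisible(x)
}

.resample_mask_nn <- function(b, a, transform) {
  # nearest-neighbour resample of mask b onto a's grid; `transform` maps
  # points in b's frame into a's frame (moving -> fixed)
  inv <- invert_transform(transform)
  w <- voxel_centers(a)
  wb <- apply_transform(w, inv)
  ijk <- sweep(wb, 2, b$origin) %*% b$orientation
  ijk <- sweep(ijk, 2, b$spacing, "/")
  ijk <- round(ijk) + 1
  d <- dim(b$mask)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- array(FALSE, dim(a$mask))
  idx <- which(ok)
  out[idx] <- b$mask[cbind(ijk[idx, 1], ijk[idx, 2], ijk[idx, 3])]
  structure(list(mask = out, spacing = a$spacing, origin = a$origin,
                 orientation = a$orientation, jaw = b$jaw),
            class = "roi_mask", empty = !any(out))
}

#' Boolean subtraction of two ROI masks
#'
#' Returns `a AND NOT b`: voxels present in `a` and absent from `b`. With
#' `a` the earlier (T0) mask and `b` the later (T2) mask this is the tissue
#' lost between the time points; swapping the arguments gives the gained
#' tissue. If `transform` is supplied, `b` is first resampled into `a`'s
#' grid by nearest neighbour through the (moving-to-fixed) jaw transform.
#'
#' @param a,b [roi_mask]s on congruent grids (or `transform` given).
#' @param transform optional [rigid_transform] mapping `b`'s frame into
#'   `a`'s.
#' @return A [roi_mask] on `a`'s grid.
#' @export
mask_subtract <- function(a, b, transform = NULL) {
  if (!is.null(transform)) {
    b <- .resample_mask_nn(b, a, transform)
  } else if (!identical(dim(a$mask), dim(b$mask))) {
    stop("mask grids are not congruent; supply the jaw transform")
  }
  structure(list(mask = a$mask & !b$mask, spacing = a$spacing,
                 origin = a$origin, orientation = a$orientation,
                 jaw = a$jaw),
            class = "roi_mask", empty = !any(a$mask & !b$mask))
}

#' Construct an axis-aligned selection box
#'
#' The volume-change selection regions ("cubes") drawn around each wisdom
#' tooth in the fixed (T0) frame, in mm.
#'
#' @param min_corner,max_corner length-3 box corners (mm),
#'   `min_corner < max_corner` componentwise.
#' @param jaw jaw tag.
#' @return An object of class `selection_box`.
#' @export
selection_box <- function(min_corner, max_corner, jaw = "maxilla") {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (!all(min_corner < max_corner))
    stop("box min corner must be strictly below max corner componentwise")
  structure(list(min = min_corner, max = max_corner, jaw = jaw),
            class = "selection_box")
}

#' Box-gated voxel-counted volume change
#'
#' Counts the change-mask voxels whose centers fall inside any selection box
#' and converts the count to millilitres. By convention tissue present at T0
#' and absent at T2 (a "lost" change mask) contributes negatively, so the
#' default `sign = -1` reports resorption/extraction as a negative volume.
#'
#' @param change a [roi_mask] (e.g. from [mask_subtract()]).
#' @param boxes a [selection_box] or list of them.
#' @param sign +1 or -1, the sign given to the counted volume (default -1,
#'   for a lost-tissue mask).
#' @return Volume in ml, with attribute `"voxels"` (the gated count). Boxes
#'   entirely outside the grid contribute zero with a warning.
#' @export
htvc <- function(change, boxes, sign = -1) {
  if (inherits(boxes, "selection_box")) boxes <- list(boxes)
  if (length(boxes) == 0L) stop("at least one selection box is required")
  w <- voxel_centers(change)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  gated <- rep(FALSE, nrow(w))
  for (b in boxes) {
    if (any(b$max < lo) || any(b$min > hi)) {
      warning("selection box lies outside the volume grid; zero contribution")
      next
    }
    gated <- gated |
      (w[, 1] >= b$min[1] & w[, 1] <= b$max[1] &
       w[, 2] >= b$min[2] & w[, 2] <= b$max[2] &
       w[, 3] >= b$min[3] & w[, 3] <= b$max[3])
  }
  count <- sum(gated & as.vector(change$mask))
  vol_ml <- sign * count * prod(change$spacing) / 1000
  attr(vol_ml, "voxels") <- count
  vol_ml
}

#' Rigid jaw alignment of serial CBCT volumes
#'
#' Aligns a moving volume to the fixed (baseline) volume for one jaw. In
#' `"manual"` mode the supplied transform is returned unchanged (the
#' operator's rotation/translation). In `"auto"` mode the initial transform
#' is refined by maximizing normalized cross-correlation of intensities over
#' a jaw sub-box, sampling the moving volume by trilinear interpolation and
#' searching the 6 rigid parameters with Nelder-Mead.
#'
#' @param moving,fixed [voxel_volume]s.
#' @param jaw jaw tag (bookkeeping only).
#' @param init initial [rigid_transform] (moving to fixed); identity if
#'   `NULL` in auto mode, required in manual mode.
#' @param mode `"auto"` or `"manual"`.
#' @param box optional [selection_box] restricting the similarity region;
#'   defaults to the whole fixed grid.
#' @param stride sampling stride over fixed voxels (default 2).
#' @param maxit Nelder-Mead iteration budget (default 400).
#' @param coarse_range half-range in mm of the initial translation grid
#'   search (default 3); the grid step is the moving volume's largest
#'   spacing.
#' @return A [rigid_transform] mapping moving into fixed, with attribute
#'   `"ncc"` (achieved similarity in auto mode).
#' @export
align_jaw <- function(moving, fixed, jaw = "maxilla", init = NULL,
                      mode = c("auto", "manual"), box = NULL, stride = 2L,
                      maxit = 400L, coarse_range = 3) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    if (is.null(init))
      stop("manual mode requires the operator-supplied transform")
    return(init)
  }
  if (is.null(init)) init <- rigid_transform()
  d <- dim(fixed$data)
  ii <- seq(1L, d[1], by = stride)
  jj <- seq(1L, d[2], by = stride)
  kk <- seq(1L, d[3], by = stride)
  ijk <- as.matrix(expand.grid(ii - 1L, jj - 1L, kk - 1L))
  w <- sweep(ijk %*% diag(fixed$spacing) %*% t(fixed$orientation), 2,
             fixed$origin, "+")
  if (!is.null(box)) {
    keep <- w[, 1] >= box$min[1] & w[, 1] <= box$max[1] &
            w[, 2] >= box$min[2] & w[, 2] <= box$max[2] &
            w[, 3] >= box$min[3] & w[, 3] <= box$max[3]
    if (sum(keep) < 100L) stop("jaw box selects too few voxels")
    ijk <- ijk[keep, , drop = FALSE]
    w <- w[keep, , drop = FALSE]
  }
  fv <- fixed$data[cbind(ijk[, 1] + 1L, ijk[, 2] + 1L, ijk[, 3] + 1L)]
  ctr <- colMeans(w)
  minv <- moving$orientation  # columns orthonormal; inverse = transpose
  dims <- dim(moving$data)
  ncc <- function(par) {
    R <- rotation_about_axis(c(1, 0, 0), par[4]) %*%
         rotation_about_axis(c(0, 1, 0), par[5]) %*%
         rotation_about_axis(c(0, 0, 1), par[6])
    tr <- compose_transform(
      rigid_transform(R, ctr - as.numeric(R %*% ctr) + par[1:3]), init)
    inv <- invert_transform(tr)
    wm <- apply_transform(w, inv)
    vox <- sweep(sweep(wm, 2, moving$origin) %*% minv, 2, moving$spacing, "/")
    mv <- cpp_trilinear(as.numeric(moving$data), as.integer(dims), vox)
    ok <- !is.na(mv)
    if (sum(ok) < 100L) return(1)
    v <- suppressWarnings(cor(fv[ok], mv[ok]))
    if (!is.finite(v)) 1 else -v
  }
  # coarse translation search first: voxel-aliasing ripples in the
  # similarity trap a local simplex search started at zero
  step <- max(moving$spacing)
  offs <- seq(-coarse_range, coarse_range, by = step)
  grid <- as.matrix(expand.grid(offs, offs, offs))
  coarse <- apply(grid, 1, function(t3) ncc(c(t3, 0, 0, 0)))
  p0 <- c(grid[which.min(coarse), ], 0, 0, 0)
  fit <- optim(p0, ncc, method = "Nelder-Mead",
               control = list(maxit = maxit,
                              parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
  if (!is.finite(fit$value) || fit$value >= 1)
    stop("similarity could not be improved; volumes may not overlap ",
         "(supply an initial transform or use manual mode)")
  par <- fit$par
  R <- rotation_about_axis(c(1, 0, 0), par[4]) %*%
       rotation_about_axis(c(0, 1, 0), par[5]) %*%
       rotation_about_axis(c(0, 0, 1), par[6])
  out <- compose_transform(
    rigid_transform(R, ctr - as.numeric(R %*% ctr) + par[1:3]), init)
  attr(out, "ncc") <- -fit$value
  out
}
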