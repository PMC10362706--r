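#' Specification for a synthetic cheek-patch phantom series
#'
#' The phantom emulates a smooth cheek-like surface patch observed at three
#' time points. World axes: x lateral (the projection direction, positive
#' toward the subject's right), y anterior-posterior, z vertical. The patch
#' is a height field `x = g(y, z)` over a square footprint, so every
#' geometric quantity has a closed form. T1/T2 differ from T0 by a known
#' rigid perturbation (scanner repositioning), optional Gaussian-bump
#' deformations of analytic volume applied along the projection direction,
#' and optional along-normal measurement noise. Laser traces are emitted as
#' the analytic curves a horizontal and a mid-sagittal vertical laser leave
#' on the (virtual) full face, consistent with the mid-sagittal plane x = 0.
#'
#' @param half_extent half side length of the patch footprint in mm
#'   (default 60).
#' @param resolution grid step in mm (default 0.5).
#' @param surface surface family: "superellipsoid-cheek" (default; a face
#'   has no continuous symmetry, so registration is fully determined),
#'   "spherical-cap" or "plane". A spherical cap leaves rotations about the
#'   sphere center unobservable to surface registration, so it suits
#'   volume-quadrature oracles, not registration tests.
#' @param apex_x lateral distance of the cheek apex from the mid-sagittal
#'   plane (mm, default 45).
#' @param curvature_radius sphere radius for the spherical cap (mm,
#'   default 110).
#' @param bumps list of Gaussian bump deformations, each a list with
#'   `center` (y, z in mm), `amplitude` (A, mm, along +x), `sigma` (mm) and
#'   `timepoints` (character subset of "T1", "T2"). Each bump adds exactly
#'   `2 * pi * A * sigma^2` mm^3 of projected volume.
#' @param perturb named list of per-time-point rigid perturbations, each a
#'   list with `angles` (x/y/z rotations, degrees, applied about the patch
#'   centroid) and `translation` (mm). Defaults emulate a few degrees / mm
#'   of repositioning between sessions.
#' @param noise_sd along-normal Gaussian noise SD in mm on T1/T2 (default 0).
#' @param laser_noise_sd noise SD on laser trace points (default 0).
#' @param seed RNG seed; the same spec is bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(half_extent = 60, resolution = 0.5,
                         surface = c("superellipsoid-cheek", "spherical-cap",
                                     "plane"),
                         apex_x = 45, curvature_radius = 110,
                         bumps = list(),
                         perturb = list(
                           T1 = list(angles = c(2, -3, 2),
                                     translation = c(3, -2, 2)),
                           T2 = list(angles = c(-3, 2, -2),
                                     translation = c(-2, 3, -2))),
                         noise_sd = 0, laser_noise_sd = 0, seed = 1L) {
  surface <- match.arg(surface)
  if (surface == "spherical-cap" &&
      curvature_radius^2 <= 2 * half_extent^2)
    stop("curvature_radius too small for the footprint")
  for (b in bumps) {
    clear <- min(half_extent - abs(b$center[1]), half_extent - abs(b$center[2]))
    if (clear < 3.72 * b$sigma)
      stop(sprintf(
        "bump at (%.1f, %.1f) with sigma %.1f mm is not fully inside the patch footprint",
        b$center[1], b$center[2], b$sigma))
    if (b$sigma <= 0 || b$amplitude == 0)
      stop("bump needs sigma > 0 and a non-zero amplitude")
  }
  structure(list(half_extent = half_extent, resolution = resolution,
                 surface = surface, apex_x = apex_x,
                 curvature_radius = curvature_radius, bumps = bumps,
                 perturb = perturb, noise_sd = noise_sd,
                 laser_noise_sd = laser_noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Analytic projected volume of a Gaussian bump
#' @param amplitude bump amplitude A in mm.
#' @param sigma bump width in mm.
#' @return volume in mm^3 (`2 * pi * A * sigma^2`).
#' @export
gaussian_bump_volume <- function(amplitude, sigma) {
  2 * pi * amplitude * sigma^2
}

.phantom_height <- function(spec, y, z) {
  switch(spec$surface,
         "plane" = rep(spec$apex_x, length(y)),
         "spherical-cap" = {
           rc <- spec$curvature_radius
           spec$apex_x - (rc - sqrt(rc^2 - y^2 - z^2))
         },
         "superellipsoid-cheek" = {
           he <- spec$half_extent
           spec$apex_x - 25 * ((abs(y) / he)^4 + (abs(z) / he)^4) / 2
         })
}

.phantom_landmarks_yz <- function() {
  list("pt'" = c(-52, 28), "al'" = c(46, 26), "ex'" = c(54, 38),
       "ch'" = c(34, -44))
}

.phantom_mandible_yz <- function() {
  rbind(c(44, -48), c(10, -55), c(-24, -52), c(-45, -36))
}

#' Generate a synthetic face-scan series with analytic ground truth
#'
#' Builds T0/T1/T2 cheek-patch scans per the [phantom_spec()], the two laser
#' traces, a landmark set (stylized but anatomically ordered: pt', al', ex',
#' ch' and a mandible lower-border list, scaled into the patch footprint),
#' and a truth record with the exact rigid perturbations and the analytic
#' projected-volume change per period.
#'
#' @param spec a [phantom_spec].
#' @return list with `scans` (named list of [surface_scan]s), `lasers`
#'   (`horizontal`, `vertical` [laser_trace]s), `landmarks` (a
#'   [landmark_set]), and `truth` (transforms per time point, added volume in
#'   mm^3 per period, bump list, noise SD).
#' @export
make_face_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  he <- spec$half_extent
  ys <- seq(-he, he, by = spec$resolution)
  zs <- seq(-he, he, by = spec$resolution)
  ny <- length(ys)
  nz <- length(zs)
  yy <- rep(ys, times = nz)
  zz <- rep(zs, each = ny)
  gx <- .phantom_height(spec, yy, zz)
  verts0 <- cbind(gx, yy, zz)

  vid <- function(i, j) (j - 1L) * ny + i
  i <- rep(seq_len(ny - 1L), times = nz - 1L)
  j <- rep(seq_len(nz - 1L), each = ny - 1L)
  a <- vid(i, j)
  b <- vid(i + 1L, j)
  cc <- vid(i + 1L, j + 1L)
  d <- vid(i, j + 1L)
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, d))

  scans <- list(T0 = surface_scan(verts0, faces, label = "T0"))
  truth_tf <- list()
  normals0 <- NULL
  for (tp in c("T1", "T2")) {
    v <- verts0
    for (bp in spec$bumps) {
      if (!(tp %in% bp$timepoints)) next
      r2 <- (yy - bp$center[1])^2 + (zz - bp$center[2])^2
      v[, 1] <- v[, 1] + bp$amplitude * exp(-r2 / (2 * bp$sigma^2))
    }
    if (spec$noise_sd > 0) {
      if (is.null(normals0)) normals0 <- .vertex_normals(verts0, faces)
      v <- v + normals0 * rnorm(nrow(v), sd = spec$noise_sd)
    }
    pert <- spec$perturb[[tp]]
    tf <- rigid_transform()
    if (!is.null(pert)) {
      R <- rotation_about_axis(c(1, 0, 0), pert$angles[1]) %*%
           rotation_about_axis(c(0, 1, 0), pert$angles[2]) %*%
           rotation_about_axis(c(0, 0, 1), pert$angles[3])
      ctr <- colMeans(verts0)
      tf <- rigid_transform(R, ctr - as.numeric(R %*% ctr) +
                                 pert$translation)
      v <- apply_transform(v, tf)
    }
    scans[[tp]] <- surface_scan(v, faces, label = tp)
    truth_tf[[tp]] <- tf
  }

  # laser traces on the virtual full face (mid-sagittal plane x = 0)
  z0 <- 25
  hx <- seq(-30, 30, by = 2)
  horiz <- cbind(hx, 62 - 0.004 * hx^2, z0)
  vz <- seq(z0 - 40, z0 + 40, by = 2)
  # the sag constants shift each fitted line off its curve; offset the
  # vertical profile so the two fitted lines cross exactly on the midline,
  # as the physical lasers do on the face
  c0 <- 62 - 0.004 * mean(hx^2) + 0.003 * mean((vz - z0)^2)
  vert <- cbind(0, c0 + 0.4 * (vz - z0) - 0.003 * (vz - z0)^2, vz)
  if (spec$laser_noise_sd > 0) {
    horiz <- horiz + rnorm(length(horiz), sd = spec$laser_noise_sd)
    vert <- vert + rnorm(length(vert), sd = spec$laser_noise_sd)
  }

  lm_yz <- .phantom_landmarks_yz()
  mb_yz <- .phantom_mandible_yz()
  sc <- he / 60  # landmark template is laid out for a 60 mm half extent
  lm_pts <- lapply(lm_yz, function(p) {
    p <- p * sc
    c(.phantom_height(spec, p[1], p[2]), p[1], p[2])
  })
  mb_pts <- t(apply(mb_yz * sc, 1, function(p)
    c(.phantom_height(spec, p[1], p[2]), p[1], p[2])))
  landmarks <- landmark_set(lm_pts, mandible_border = mb_pts, side = "right")

  vol_at <- function(tp) {
    s <- 0
    for (bp in spec$bumps)
      if (tp %in% bp$timepoints)
        s <- s + gaussian_bump_volume(bp$amplitude, bp$sigma)
    s
  }
  truth <- list(
    transforms = truth_tf,
    added_volume_mm3 = c("T1-T0" = vol_at("T1"),
                         "T2-T0" = vol_at("T2"),
                         "T2-T1" = vol_at("T2") - vol_at("T1")),
    bumps = spec$bumps, noise_sd = spec$noise_sd)

  list(scans = scans,
       lasers = list(
         horizontal = laser_trace(horiz, "horizontal-complete"),
         vertical = laser_trace(vert, "vertical")),
       landmarks = landmarks,
       truth = truth)
}

#' Specification for a synthetic CBCT phantom pair
#'
#' A voxel phantom with a soft-tissue background, a cortical-bone box shell,
#' a marrow interior, and a "tooth" sphere of known analytic volume inside
#' the shell. The T2 volume lacks the tooth (extraction), so the
#' threshold-segmentation / Boolean-subtraction / voxel-counting pipeline
#' should recover minus the analytic sphere volume.
#'
#' @param dims grid dimensions (default 112^3, sized so the default tooth
#'   fits inside the marrow cavity with margin).
#' @param spacing voxel spacing in mm (default 0.25 isotropic).
#' @param background soft-tissue intensity (default 100).
#' @param bone_intensity cortical shell intensity (default 3000).
#' @param marrow_intensity interior intensity (default 200).
#' @param tooth_intensity tooth intensity (default 2800).
#' @param tooth_radius tooth sphere radius in mm (default 8).
#' @param tooth_center sphere center in mm; default the grid center.
#' @param removal if `TRUE` (default) the tooth is absent at T2.
#' @param noise_sd Gaussian intensity noise SD (default 0).
#' @param seed RNG seed.
#' @return An object of class `cbct_phantom_spec`.
#' @export
cbct_phantom_spec <- function(dims = c(112, 112, 112),
                              spacing = c(0.25, 0.25, 0.25),
                              background = 100, bone_intensity = 3000,
                              marrow_intensity = 200,
                              tooth_intensity = 2800, tooth_radius = 8,
                              tooth_center = NULL, removal = TRUE,
                              noise_sd = 0, seed = 1L) {
  extent <- (dims - 1) * spacing
  if (is.null(tooth_center)) tooth_center <- extent / 2
  if (any(tooth_center - tooth_radius < 0) ||
      any(tooth_center + tooth_radius > extent))
    stop("tooth sphere extends outside the grid")
  if (tooth_radius <= 0) stop("tooth_radius must be positive")
  # cortical shell: box walls between 12% and 88% of the extent, 1.5 mm thick
  shell_lo <- 0.12 * extent
  shell_hi <- 0.88 * extent
  wall <- 1.5
  if (any(tooth_center - tooth_radius < shell_lo + wall) ||
      any(tooth_center + tooth_radius > shell_hi - wall))
    stop("tooth sphere must lie inside the marrow cavity ",
         "(enlarge the grid or shrink the tooth)")
  structure(list(dims = as.integer(dims), spacing = as.numeric(spacing),
                 background = background, bone_intensity = bone_intensity,
                 marrow_intensity = marrow_intensity,
                 tooth_intensity = tooth_intensity,
                 tooth_radius = tooth_radius,
                 tooth_center = as.numeric(tooth_center),
                 shell_lo = shell_lo, shell_hi = shell_hi, wall = wall,
                 removal = isTRUE(removal), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cbct_phantom_spec")
}

#' Generate a synthetic CBCT series pair with known removed volume
#'
#' @param spec a [cbct_phantom_spec].
#' @param dir optional directory; if given, `<dir>/T0` and `<dir>/T2` DICOM
#'   series are written.
#' @return list with `t0`, `t2` ([voxel_volume]s), `truth` (analytic removed
#'   volume in mm^3, exact voxel count of the sphere, tooth geometry) and,
#'   if written, `dirs`.
#' @export
make_cbct_series <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cbct_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dims
  sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  base <- array(spec$background, d)

  lo <- spec$shell_lo
  hi <- spec$shell_hi
  w <- spec$wall
  inbox <- function(a, b)
    outer(outer(xs >= a[1] & xs <= b[1], ys >= a[2] & ys <= b[2], "&"),
          zs >= a[3] & zs <= b[3], "&")
  box_out <- inbox(lo, hi)
  box_in <- inbox(lo + w, hi - w)
  base[box_out] <- spec$bone_intensity
  base[box_in] <- spec$marrow_intensity

  r2 <- outer(outer((xs - spec$tooth_center[1])^2,
                    (ys - spec$tooth_center[2])^2, "+"),
              (zs - spec$tooth_center[3])^2, "+")
  sphere <- r2 <= spec$tooth_radius^2
  t0 <- base
  t0[sphere] <- spec$tooth_intensity
  t2 <- base
  if (!spec$removal) t2[sphere] <- spec$tooth_intensity
  if (spec$noise_sd > 0) {
    t0 <- t0 + array(rnorm(length(t0), sd = spec$noise_sd), d)
    t2 <- t2 + array(rnorm(length(t2), sd = spec$noise_sd), d)
  }
  v0 <- voxel_volume(t0, sp)
  v2 <- voxel_volume(t2, sp)
  truth <- list(
    removed_volume_mm3 = if (spec$removal)
      4 / 3 * pi * spec$tooth_radius^3 else 0,
    sphere_voxels = sum(sphere),
    tooth_center = spec$tooth_center, tooth_radius = spec$tooth_radius)
  out <- list(t0 = v0, t2 = v2, truth = truth)
  if (!is.null(dir)) {
    d0 <- file.path(dir, "T0")
    d2 <- file.path(dir, "T2")
    write_dicom_series(v0, d0, series_uid = "1.2.826.0.1.3680043.9999.10")
    write_dicom_series(v2, d2, series_uid = "1.2.826.0.1.3680043.9999.20")
    out$dirs <- c(T0 = d0, T2 = d2)
  }
  out
}

#' Generate a two-way random-effects rater table
#'
#' `value[i, j] = mu + subject_i + rater_j + error_ij` with independent
#' normal components, so the expected ICC(2,1) equals
#' `var_subject / (var_subject + var_rater + var_error)`.
#'
#' @param n subjects (rows), >= 2.
#' @param k raters (columns), >= 2.
#' @param var_subject,var_rater,var_error variance components (>= 0).
#' @param mu grand mean (default 10).
#' @param seed RNG seed.
#' @return n x k numeric matrix with attribute `"expected_icc"`.
#' @export
make_rater_table <- function(n, k, var_subject, var_rater, var_error,
                             mu = 10, seed = 1L) {
  if (n < 2L || k < 2L) stop("need n >= 2 and k >= 2")
  if (any(c(var_subject, var_rater, var_error) < 0))
    stop("variances must be >= 0")
  set.seed(seed)
  s <- rnorm(n, sd = sqrt(var_subject))
  r <- rnorm(k, sd = sqrt(var_rater))
  e <- matrix(rnorm(n * k, sd = sqrt(var_error)), n, k)
  tab <- mu + outer(s, rep(1, k)) + outer(rep(1, n), r) + e
  attr(tab, "expected_icc") <-
    if (var_subject + var_rater + var_error == 0) 1 else
      var_subject / (var_subject + var_rater + var_error)
  tab
}
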