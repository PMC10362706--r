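.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full soft-tissue (projection method) pipeline
#'
#' Composition of the measurement steps on a baseline scan plus one or more
#' follow-up scans: (1) build the mid-sagittal frame from the laser traces,
#' (2) extract the baseline buccal patch from the landmarks, (3) register
#' each follow-up scan to the upper third of the baseline, (4) transfer the
#' boundary with the extruded ring model and cut each registered scan,
#' (5) measure STV per time point and STVC per period, and (6) run the
#' deviation (3D-compare) analysis per period.
#'
#' Inputs may be in-memory objects or file paths (OBJ scans, OBJ laser
#' traces, CSV landmarks).
#'
#' @param t0 baseline [surface_scan] or OBJ path.
#' @param scans named list of follow-up [surface_scan]s or OBJ paths (names
#'   are time-point labels, e.g. `list(T1 = ..., T2 = ...)`).
#' @param lasers list with `horizontal` and `vertical` [laser_trace]s or OBJ
#'   paths.
#' @param landmarks a [landmark_set] or CSV path.
#' @param side face side to measure.
#' @param half_length ring sweep half-length in mm (default 10).
#' @param upper_fraction registration crop fraction (default 1/3).
#' @param max_dist deviation correspondence cutoff in mm (default 10).
#' @param out optional output directory for JSON/CSV reports.
#' @return list with `frame`, `volumes` (data.frame: timepoint, stv_ml,
#'   patch area), `changes` (data.frame: period, stvc_ml), `deviation`
#'   (data.frame: period, mu, sd, rms, n), `registration` (per scan:
#'   transform + QC), and `params`.
#' @export
run_soft_pipeline <- function(t0, scans, lasers, landmarks,
                              side = c("right", "left"), half_length = 10,
                              upper_fraction = 1 / 3, max_dist = 10,
                              out = NULL) {
  side <- match.arg(side)
  t0 <- .stage("mesh_io", {
    if (is.character(t0)) read_obj(t0, label = "T0") else t0
  })
  scans <- .stage("mesh_io", {
    if (is.null(names(scans)) || any(names(scans) == ""))
      stop("follow-up scans must be a named list (e.g. T1, T2)")
    lapply(seq_along(scans), function(i) {
      s <- scans[[i]]
      if (is.character(s)) read_obj(s, label = names(scans)[i]) else s
    }) -> ss
    names(ss) <- names(scans)
    ss
  })
  lasers <- .stage("mesh_io", {
    h <- lasers$horizontal
    v <- lasers$vertical
    if (is.character(h)) h <- read_laser_obj(h, "horizontal-complete")
    if (is.character(v)) v <- read_laser_obj(v, "vertical")
    list(horizontal = h, vertical = v)
  })
  frame <- .stage("sagittal_frame",
                  build_frame(lasers$horizontal, lasers$vertical))
  landmarks <- .stage("region", {
    if (is.character(landmarks))
      read_landmarks(landmarks, scan = t0, side = side)
    else landmarks
  })
  patch0 <- .stage("region", extract_buccal(t0, landmarks, side = side))
  fixed_region <- .stage("registration",
                         crop_upper_third(t0, frame, upper_fraction))
  ring <- .stage("projection",
                 extrude_ring(patch0, frame$projection_direction, half_length))

  v0 <- .stage("projection", stv(patch0, frame))
  volumes <- data.frame(timepoint = "T0", stv_ml = v0$stv,
                        area_mm2 = v0$area, stringsAsFactors = FALSE)
  results <- list(T0 = v0)
  patches <- list(T0 = patch0)
  registration <- list()
  for (tp in names(scans)) {
    tf <- .stage("registration",
                 icp_register(scans[[tp]], fixed_region))
    reg <- apply_transform(scans[[tp]], tf)
    registration[[tp]] <- list(transform = tf,
                               converged = isTRUE(attr(tf, "converged")),
                               rms_mm = attr(tf, "rms"),
                               iterations = attr(tf, "iterations"))
    patch <- .stage("projection", boolean_cut(ring, reg))
    vres <- .stage("projection", stv(patch, frame))
    results[[tp]] <- vres
    patches[[tp]] <- patch
    volumes <- rbind(volumes,
                     data.frame(timepoint = tp, stv_ml = vres$stv,
                                area_mm2 = vres$area,
                                stringsAsFactors = FALSE))
  }

  tps <- names(results)
  changes <- NULL
  deviation <- NULL
  if (length(tps) > 1L) {
    pairs <- utils::combn(seq_along(tps), 2)
    for (c0 in seq_len(ncol(pairs))) {
      iearly <- pairs[1, c0]
      ilate <- pairs[2, c0]
      dv <- stvc(results[[iearly]], results[[ilate]])
      changes <- rbind(changes,
                       data.frame(period = attr(dv, "period"),
                                  stvc_ml = as.numeric(dv),
                                  stringsAsFactors = FALSE))
      cmp <- .stage("deviation",
                    compare_surfaces(patches[[iearly]], patches[[ilate]],
                                     max_dist = max_dist))
      deviation <- rbind(deviation,
                         data.frame(period = attr(dv, "period"),
                                    mu = cmp$mu, sd = cmp$sd, rms = cmp$rms,
                                    n = cmp$n, stringsAsFactors = FALSE))
    }
  }
  params <- list(side = side, half_length = half_length,
                 upper_fraction = upper_fraction, max_dist = max_dist)
  report <- list(frame = frame, volumes = volumes, changes = changes,
                 deviation = deviation, registration = registration,
                 params = params)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(volumes = volumes, changes = changes, deviation = deviation,
           params = params,
           registration = lapply(registration, function(r)
             list(converged = r$converged, rms_mm = r$rms_mm,
                  iterations = r$iterations))),
      file.path(out, "soft_tissue_report.json"),
      digits = NA, auto_unbox = TRUE, dataframe = "rows")
    write.csv(volumes, file.path(out, "stv.csv"), row.names = FALSE)
    if (!is.null(changes))
      write.csv(changes, file.path(out, "stvc.csv"), row.names = FALSE)
    if (!is.null(deviation))
      write.csv(deviation, file.path(out, "deviation.csv"), row.names = FALSE)
  }
  report
}

#' Run the full hard-tissue (CBCT voxel-counting) pipeline
#'
#' Composition: per-jaw rigid alignment of the later volume to the baseline,
#' threshold segmentation of both, Boolean subtraction in both directions,
#' and box-gated voxel counting. HTVC is reported as gained minus lost
#' volume in ml, so tissue present at T0 and absent at T2 (extraction,
#' resorption) is negative.
#'
#' @param t0,t2 [voxel_volume]s or DICOM series directories.
#' @param boxes a [selection_box] or list of them (per jaw).
#' @param lower,upper segmentation window (defaults 550 / 3300).
#' @param transforms optional named list of per-jaw [rigid_transform]s
#'   (moving T2 into T0); identity when omitted and `auto_align = FALSE`.
#' @param auto_align refine alignment by intensity similarity (default
#'   FALSE: congruent phantom grids need no alignment).
#' @param out optional output directory for the JSON report.
#' @return list with per-jaw rows (`jaw`, `lost_ml`, `gained_ml`, `htvc_ml`),
#'   `htvc_ml` (summed over jaws), QC flags and `params`.
#' @export
run_hard_pipeline <- function(t0, t2, boxes, lower = 550, upper = 3300,
                              transforms = NULL, auto_align = FALSE,
                              out = NULL) {
  t0 <- .stage("cbct", if (is.character(t0)) read_dicom_series(t0) else t0)
  t2 <- .stage("cbct", if (is.character(t2)) read_dicom_series(t2) else t2)
  if (inherits(boxes, "selection_box")) boxes <- list(boxes)
  jaws <- unique(vapply(boxes, function(b) b$jaw, ""))
  rows <- NULL
  flags <- list()
  total <- 0
  for (jaw in jaws) {
    jb <- boxes[vapply(boxes, function(b) identical(b$jaw, jaw), TRUE)]
    tf <- if (!is.null(transforms) && !is.null(transforms[[jaw]]))
      transforms[[jaw]] else NULL
    if (auto_align)
      tf <- .stage("cbct", align_jaw(t2, t0, jaw = jaw, init = tf,
                                     mode = "auto", box = jb[[1]]))
    m0 <- .stage("cbct", threshold_segment(t0, lower, upper, jaw = jaw))
    m2 <- .stage("cbct", threshold_segment(t2, lower, upper, jaw = jaw))
    if (attr(m0, "empty") || attr(m2, "empty"))
      flags[[jaw]] <- "empty threshold mask"
    # both change masks are evaluated on the fixed (T0) grid, where the
    # selection boxes are drawn
    m2r <- if (is.null(tf)) m2 else .stage("cbct", .resample_mask_nn(m2, m0, tf))
    lost <- .stage("cbct", mask_subtract(m0, m2r))
    gained <- .stage("cbct", mask_subtract(m2r, m0))
    lost_ml <- abs(as.numeric(htvc(lost, jb, sign = -1)))
    gained_ml <- as.numeric(htvc(gained, jb, sign = 1))
    h <- gained_ml - lost_ml
    total <- total + h
    rows <- rbind(rows, data.frame(jaw = jaw, lost_ml = lost_ml,
                                   gained_ml = gained_ml, htvc_ml = h,
                                   stringsAsFactors = FALSE))
  }
  params <- list(lower = lower, upper = upper, auto_align = auto_align)
  report <- list(per_jaw = rows, htvc_ml = total, flags = flags,
                 params = params)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[c("per_jaw", "htvc_ml", "flags", "params")],
                         file.path(out, "hard_tissue_report.json"),
                         digits = NA, auto_unbox = TRUE, dataframe = "rows")
  }
  report
}
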