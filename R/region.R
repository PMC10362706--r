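#' Foot of the perpendicular from the cheilion onto the mandible border
#'
#' The chin footpoint cf' is constructed by dropping a perpendicular from the
#' cheilion ch' onto the lower border of the mandible: it is the point of the
#' piecewise-linear border polyline closest to ch' (clamped to segment
#' endpoints where the foot falls outside a segment).
#'
#' @param ch cheilion, length-3 point (mm).
#' @param mandible_border ordered k x 3 matrix of border points, k >= 2.
#' @return list with `point` (the footpoint), `segment` (index of the border
#'   segment it lies on) and `t` (position along that segment in \[0, 1\]).
#' @export
chin_footpoint <- function(ch, mandible_border) {
  ch <- as.numeric(ch)
  b <- as.matrix(mandible_border)
  if (is.null(b) || nrow(b) < 2L)
    stop("mandible border needs at least 2 points")
  best <- list(d2 = Inf, point = NULL, segment = NA_integer_, t = NA_real_)
  for (i in seq_len(nrow(b) - 1L)) {
    a <- b[i, ]
    d <- b[i + 1L, ] - a
    len2 <- sum(d^2)
    t <- if (len2 < 1e-300) 0 else max(0, min(1, sum((ch - a) * d) / len2))
    p <- a + t * d
    d2 <- sum((ch - p)^2)
    if (d2 < best$d2) best <- list(d2 = d2, point = p, segment = i, t = t)
  }
  best$d2 <- NULL
  best
}

.edge_graph <- function(scan) {
  f <- scan$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(.edge_keys(e, nrow(scan$vertices) + 1)), , drop = FALSE]
  w <- .row_norms(scan$vertices[e[, 1], , drop = FALSE] -
                  scan$vertices[e[, 2], , drop = FALSE])
  g <- igraph::make_empty_graph(n = nrow(scan$vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$weight <- w
  g
}

.nearest_vertex <- function(scan, p) {
  which.min(.row_norms(sweep(scan$vertices, 2, as.numeric(p))))
}

#' Shortest edge-walk between two points on a scan
#'
#' Formalizes the interactive "draw" operation connecting landmarks as the
#' shortest path over mesh edges (Dijkstra, Euclidean edge weights) between
#' the mesh vertices nearest to `a` and `b`.
#'
#' @param scan a [surface_scan].
#' @param a,b 3D points near the surface (mm).
#' @param graph optional pre-built edge graph (as built internally), to avoid
#'   rebuilding it for repeated queries on the same scan.
#' @return integer vector of vertex indices along the path, from the vertex
#'   nearest `a` to the vertex nearest `b`; consecutive entries share a mesh
#'   edge. Attribute `"length"` holds the path length in mm.
#' @export
surface_path <- function(scan, a, b, graph = NULL) {
  g <- if (is.null(graph)) .edge_graph(scan) else graph
  va <- .nearest_vertex(scan, a)
  vb <- .nearest_vertex(scan, b)
  sp <- igraph::shortest_paths(g, from = va, to = vb, output = "both")
  path <- as.integer(sp$vpath[[1]])
  if (length(path) == 0L || (length(path) == 1L && va != vb))
    stop("no surface path: vertices lie in disconnected mesh components")
  len <- if (length(sp$epath[[1]]) == 0L) 0 else
    sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
  attr(path, "length") <- len
  path
}

.face_adjacency_components <- function(faces, loop_edges) {
  # components of the face-adjacency graph after cutting along loop edges
  nf <- nrow(faces)
  base <- max(faces) + 1
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- .edge_keys(e, base)
  fid <- rep(seq_len(nf), 3L)
  loop_key <- if (nrow(loop_edges)) .edge_keys(loop_edges, base) else numeric(0)
  ord <- order(key)
  key_s <- key[ord]
  fid_s <- fid[ord]
  n <- length(key_s)
  same <- key_s[-n] == key_s[-1]
  pair_i <- fid_s[-n][same]
  pair_j <- fid_s[-1][same]
  pair_key <- key_s[-n][same]
  keep <- !(pair_key %in% loop_key)
  gf <- igraph::make_empty_graph(n = nf, directed = FALSE)
  if (any(keep))
    gf <- igraph::add_edges(gf, rbind(pair_i[keep], pair_j[keep]))
  igraph::components(gf)$membership
}

.open_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ek <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- .edge_keys(ek, max(faces) + 1)
  tab <- sort(key)
  singles <- tab[c(diff(tab) != 0, TRUE) & c(TRUE, diff(tab) != 0)]
  ek[key %in% singles, , drop = FALSE]
}

.submesh <- function(scan, face_ids, label = scan$label) {
  faces <- scan$faces[face_ids, , drop = FALSE]
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(scan$vertices))
  remap[used] <- seq_along(used)
  list(vertices = scan$vertices[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3),
       parent_vertices = used, label = label)
}

#' Construct a buccal patch object
#' @param vertices,faces patch sub-mesh (faces index into `vertices`).
#' @param boundary ordered (closed) loop of indices into `vertices`.
#' @param side face side.
#' @param label time-point tag.
#' @return An object of class `buccal_patch`.
#' @export
buccal_patch <- function(vertices, faces, boundary, side = "right",
                         label = "") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices,
                 faces = faces,
                 boundary = as.integer(boundary),
                 side = side, label = label),
            class = "buccal_patch")
}

#' @export
print.buccal_patch <- function(x, ...) {
  cat(sprintf("buccal_patch (%s, %s): %d vertices, %d faces, area %.1f mm^2\n",
              x$side, x$label, nrow(x$vertices), nrow(x$faces),
              patch_area(x)))
  invisible(x)
}

#' Total area of a patch in mm^2
#' @param patch a [buccal_patch] or [surface_scan].
#' @return numeric scalar, mm^2.
#' @export
patch_area <- function(patch) {
  sum(.row_norms(.face_vector_areas(patch$vertices, patch$faces)))
}

#' Extract the buccal region bounded by landmark-connecting surface paths
#'
#' Assembles the buccal boundary loop on the scan: surface paths pt' to al',
#' al' to ex', ex' to ch', ch' to cf' (cf' computed from ch' and the mandible
#' border via [chin_footpoint()]), then along the remaining mandible border
#' points back to pt'. The enclosed sub-mesh is the face-adjacency component,
#' after cutting along the loop, that contains no open mesh-border edge
#' outside the loop.
#'
#' @param scan a [surface_scan] (the baseline scan).
#' @param landmarks a [landmark_set] with pt', al', ex', ch' and a mandible
#'   border (cf' is accepted if supplied, otherwise constructed).
#' @param side face side tag carried to the patch.
#' @return A [buccal_patch]; indices into the parent scan are attached as
#'   attribute `"parent_vertices"`.
#' @export
extract_buccal <- function(scan, landmarks, side = landmarks$side) {
  need <- c("pt'", "al'", "ex'", "ch'")
  miss <- setdiff(need, names(landmarks$points))
  if (length(miss))
    stop("missing landmark(s): ", paste(miss, collapse = ", "))
  if (is.null(landmarks$mandible_border) && is.null(landmarks$points[["cf'"]]))
    stop("missing landmark(s): mandible border (needed to construct cf')")

  lp <- landmarks$points
  mb <- landmarks$mandible_border
  if (!is.null(lp[["cf'"]])) {
    cf <- lp[["cf'"]]
    seg_after <- if (is.null(mb)) integer(0) else
      chin_footpoint(lp[["ch'"]], mb)$segment
  } else {
    foot <- chin_footpoint(lp[["ch'"]], mb)
    cf <- foot$point
    seg_after <- foot$segment
  }
  # boundary waypoints in loop order
  waypoints <- c(list(lp[["pt'"]], lp[["al'"]], lp[["ex'"]], lp[["ch'"]], cf),
                 if (!is.null(mb) && length(seg_after) &&
                     seg_after + 1L <= nrow(mb))
                   lapply(seq(seg_after + 1L, nrow(mb)),
                          function(i) mb[i, ]))
  g <- .edge_graph(scan)
  loop <- integer(0)
  nw <- length(waypoints)
  for (i in seq_len(nw)) {
    p <- surface_path(scan, waypoints[[i]], waypoints[[if (i == nw) 1L else i + 1L]],
                      graph = g)
    if (length(loop) && loop[length(loop)] == p[1])
      p <- p[-1]
    loop <- c(loop, p)
  }
  if (loop[length(loop)] != loop[1])
    stop("buccal boundary loop failed to close")
  loop <- loop[-length(loop)]
  if (length(unique(loop)) < length(loop)) {
    # a vertex visited twice pinches the loop; keep the longest simple cycle
    dup <- loop[duplicated(loop)]
    for (d in dup) {
      at <- which(loop == d)
      if (length(at) > 1L) {
        inner <- seq(at[1] + 1L, at[2])
        if (length(inner) < length(loop) / 2)
          loop <- loop[-inner]
        else
          loop <- loop[seq(at[1] + 1L, at[2])]
      }
    }
  }
  if (length(loop) < 3L) stop("degenerate buccal boundary loop")
  loop_edges <- cbind(loop, c(loop[-1], loop[1]))

  memb <- .face_adjacency_components(scan$faces, loop_edges)
  base <- max(scan$faces) + 1
  loop_key <- .edge_keys(loop_edges, base)
  open <- .open_edges(scan$faces)
  open_key <- .edge_keys(open, base)
  leaky_vert <- unique(as.integer(open[!(open_key %in% loop_key), ,
                                       drop = FALSE]))
  f1 <- scan$faces
  face_touches_border <- (f1[, 1] %in% leaky_vert) |
    (f1[, 2] %in% leaky_vert) | (f1[, 3] %in% leaky_vert)
  comp_ids <- sort(unique(memb))
  closed_comps <- comp_ids[!vapply(comp_ids, function(cid)
    any(face_touches_border[memb == cid]), logical(1))]
  if (length(closed_comps) == 0L)
    stop("flood fill reached the scan border: boundary loop leaks")
  if (length(closed_comps) > 1L) {
    areas <- vapply(closed_comps, function(cid)
      sum(.row_norms(.face_vector_areas(scan$vertices,
                                        scan$faces[memb == cid, , drop = FALSE]))),
      numeric(1))
    stop("ambiguous enclosed region; component areas (mm^2): ",
         paste(sprintf("%.1f", areas), collapse = ", "))
  }
  sub <- .submesh(scan, which(memb == closed_comps))
  remap <- integer(nrow(scan$vertices))
  remap[sub$parent_vertices] <- seq_along(sub$parent_vertices)
  bl <- remap[loop]
  if (any(bl == 0L))
    stop("boundary loop vertices missing from the enclosed region")
  out <- buccal_patch(sub$vertices, sub$faces, bl, side = side,
                      label = scan$label)
  attr(out, "parent_vertices") <- sub$parent_vertices
  out
}

#' Write a patch boundary loop as CSV of coordinates
#' @param patch a [buccal_patch].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_boundary_csv <- function(patch, path) {
  b <- patch$vertices[patch$boundary, , drop = FALSE]
  write.csv(data.frame(x = b[, 1], y = b[, 2], z = b[, 3]), path,
            row.names = FALSE)
  invisible(path)
}
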