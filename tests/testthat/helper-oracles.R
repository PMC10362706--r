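# Independent oracle implementations used to cross-check the package's
# geometry kernels. They are deliberately simple and O(n^2)-ish: correctness
# over speed, and a different algorithm than the implementation under test.

# Dense-loop Dijkstra over a vertex/edge list (second implementation).
oracle_dijkstra_cost <- function(vertices, faces, from, to) {
  n <- nrow(vertices)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  w <- sqrt(rowSums((vertices[e[, 1], , drop = FALSE] -
                     vertices[e[, 2], , drop = FALSE])^2))
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- rbind(adj[[e[i, 1]]], c(e[i, 2], w[i]))
    adj[[e[i, 2]]] <- rbind(adj[[e[i, 2]]], c(e[i, 1], w[i]))
  }
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[from] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    if (u == to) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (!is.null(nb))
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        alt <- dist[u] + nb[r, 2]
        if (alt < dist[v]) dist[v] <- alt
      }
  }
  dist[to]
}

# Winding-number point-in-polygon (different algorithm from the crossing
# test in the compiled kernel).
oracle_in_polygon <- function(poly, pts) {
  n <- nrow(poly)
  vapply(seq_len(nrow(pts)), function(q) {
    p <- pts[q, ]
    a <- sweep(poly, 2, p)
    b <- a[c(2:n, 1), , drop = FALSE]
    ang <- atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
                 a[, 1] * b[, 1] + a[, 2] * b[, 2])
    abs(sum(ang)) > pi
  }, logical(1))
}

# Closest point on a triangle soup by brute force over all faces.
oracle_closest_dist <- function(vertices, faces, q) {
  best <- Inf
  for (f in seq_len(nrow(faces))) {
    a <- vertices[faces[f, 1], ]
    b <- vertices[faces[f, 2], ]
    cc <- vertices[faces[f, 3], ]
    # dense barycentric sampling: adequate oracle accuracy for test scales
    s <- seq(0, 1, length.out = 41)
    for (u in s) for (v in s[s <= 1 - u + 1e-12]) {
      p <- (1 - u - v) * a + u * b + v * cc
      d <- sqrt(sum((p - q)^2))
      if (d < best) best <- d
    }
  }
  best
}

# A small flat rectangular grid scan (z = 0), nx x ny vertices.
flat_grid_scan <- function(nx = 11, ny = 11, step = 1, label = "T0") {
  xs <- (seq_len(nx) - 1) * step
  ys <- (seq_len(ny) - 1) * step
  v <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  vid <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
             cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  surface_scan(v, f, label = label)
}

# A square planar patch of side `side` mm parallel to the x = 0 plane at
# distance `dist`, with its boundary loop, as a buccal_patch.
planar_square_patch <- function(side = 20, dist = 30, step = 1,
                                side_tag = "right", label = "T0") {
  n <- round(side / step) + 1L
  ys <- seq(0, side, length.out = n)
  zs <- seq(0, side, length.out = n)
  v <- cbind(dist, rep(ys, times = n), rep(zs, each = n))
  vid <- function(i, j) (j - 1L) * n + i
  i <- rep(seq_len(n - 1L), times = n - 1L)
  j <- rep(seq_len(n - 1L), each = n - 1L)
  f <- rbind(cbind(vid(i, j), vid(i + 1L, j), vid(i + 1L, j + 1L)),
             cbind(vid(i, j), vid(i + 1L, j + 1L), vid(i, j + 1L)))
  loop <- c(vid(seq_len(n), 1L), vid(n, 2:n), vid((n - 1L):1L, n),
            vid(1L, (n - 1L):2L))
  buccal_patch(v, f, loop, side = side_tag, label = label)
}

# Canonical frame: mid-sagittal plane x = 0, vertical axis +z, projection
# direction +x, built from analytic laser traces.
canonical_frame <- function() {
  hx <- seq(-30, 30, by = 2)
  horiz <- laser_trace(cbind(hx, 60 - 0.004 * hx^2, 0), "horizontal-complete")
  vz <- seq(-30, 30, by = 2)
  c0 <- 60 - 0.004 * mean(hx^2) + 0.002 * mean(vz^2)
  vert <- laser_trace(cbind(0, c0 + 0.3 * vz - 0.002 * vz^2, vz), "vertical")
  build_frame(horiz, vert)
}
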