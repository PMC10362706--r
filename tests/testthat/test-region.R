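test_that("chin_footpoint drops the perpendicular onto the border", {
  # axis-aligned foot
  got <- chin_footpoint(c(0, 10, 0), rbind(c(-5, 0, 0), c(5, 0, 0)))
  expect_equal(got$point, c(0, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  # beyond a segment end: clamped to the endpoint
  got2 <- chin_footpoint(c(10, 10, 0), rbind(c(-5, 0, 0), c(5, 0, 0)))
  expect_equal(got2$point, c(5, 0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(chin_footpoint(c(0, 0, 0), matrix(0, 1, 3)), "at least 2")
})

test_that("chin_footpoint matches a dense-sampling oracle on a random polyline", {
  set.seed(21)
  for (trial in 1:5) {
    border <- cbind(sort(runif(6, -20, 20)), rnorm(6, sd = 5), rnorm(6, sd = 5))
    ch <- rnorm(3, sd = 10)
    got <- chin_footpoint(ch, border)
    # oracle: brute-force min over densely sampled border points
    dense <- do.call(rbind, lapply(seq_len(nrow(border) - 1), function(i) {
      t <- seq(0, 1, length.out = 20001)
      outer(1 - t, border[i, ]) + outer(t, border[i + 1, ])
    }))
    dmin <- min(sqrt(rowSums(sweep(dense, 2, ch)^2)))
    expect_equal(sqrt(sum((got$point - ch)^2)), dmin, tolerance = 1e-6)
  }
})

test_that("surface paths follow rows on a flat grid and bound length below", {
  scan <- flat_grid_scan(21, 21)
  p <- surface_path(scan, c(2, 5, 0), c(18, 5, 0))
  # straight along-row path: all vertices share y = 5
  expect_true(all(scan$vertices[p, 2] == 5))
  expect_equal(attr(p, "length"), 16)
  # metric lower bound on arbitrary endpoints
  a <- c(1, 2, 0); b <- c(17, 15, 0)
  p2 <- surface_path(scan, a, b)
  va <- scan$vertices[p2[1], ]; vb <- scan$vertices[p2[length(p2)], ]
  expect_gte(attr(p2, "length"), sqrt(sum((va - vb)^2)) - 1e-12)
  # consecutive path vertices share a mesh edge (grid neighbours)
  dxy <- diff(scan$vertices[p2, 1:2])
  steps <- sqrt(rowSums(dxy^2))
  expect_true(all(steps <= sqrt(2) + 1e-9))
})

test_that("surface path cost equals an independent Dijkstra implementation", {
  ph <- make_face_series(phantom_spec(resolution = 6, seed = 8))
  s <- ph$scans$T0
  set.seed(31)
  for (trial in 1:4) {
    ab <- sample(nrow(s$vertices), 2)
    p <- surface_path(s, s$vertices[ab[1], ], s$vertices[ab[2], ])
    oracle <- oracle_dijkstra_cost(s$vertices, s$faces, ab[1], ab[2])
    expect_equal(attr(p, "length"), oracle, tolerance = 1e-9)
  }
})

test_that("extract_buccal matches 2D point-in-loop classification on the phantom", {
  ph <- make_face_series(phantom_spec(resolution = 3, seed = 9))
  patch <- extract_buccal(ph$scans$T0, ph$landmarks)
  parent <- attr(patch, "parent_vertices")
  # oracle: classify parent-scan face centroids against the projected loop
  s <- ph$scans$T0
  loop3 <- patch$vertices[patch$boundary, , drop = FALSE]
  poly <- loop3[, c(2, 3)]                     # (y, z) footprint coordinates
  cen <- (s$vertices[s$faces[, 1], ] + s$vertices[s$faces[, 2], ] +
          s$vertices[s$faces[, 3], ]) / 3
  inside <- oracle_in_polygon(poly, cen[, c(2, 3)])
  # patch faces (mapped back to parent indexing)
  pf <- matrix(parent[patch$faces], ncol = 3)
  key <- function(f) paste(f[, 1], f[, 2], f[, 3])
  expect_setequal(key(pf), key(s$faces[inside, , drop = FALSE]))
  # area strictly between 0 and the scan area
  expect_gt(patch_area(patch), 0)
  expect_lt(patch_area(patch), patch_area(s))
  # boundary vertices lie on the loop
  open_b <- patch$vertices[patch$boundary, ]
  expect_true(all(is.finite(open_b)))
})

test_that("extract_buccal is deterministic and demands its landmarks", {
  ph <- make_face_series(phantom_spec(resolution = 3, seed = 9))
  p1 <- extract_buccal(ph$scans$T0, ph$landmarks)
  p2 <- extract_buccal(ph$scans$T0, ph$landmarks)
  expect_identical(p1$faces, p2$faces)
  expect_identical(p1$boundary, p2$boundary)

  lm <- ph$landmarks
  lm$points[["ex'"]] <- NULL
  expect_error(extract_buccal(ph$scans$T0, lm), "missing landmark.*ex'")
  lm2 <- ph$landmarks
  lm2$mandible_border <- NULL
  expect_error(extract_buccal(ph$scans$T0, lm2), "mandible")
})

test_that("a loop along the entire mesh boundary yields the whole mesh", {
  patch0 <- planar_square_patch(side = 10, dist = 5, step = 1)
  scan <- surface_scan(patch0$vertices, patch0$faces)
  # walk the boundary loop as landmarks: corners as pt'/al'/ex'/ch', the
  # remaining edge as the mandible border
  v <- patch0$vertices
  b <- patch0$boundary
  corner <- function(p) v[b[which.min(rowSums(sweep(v[b, ], 2, p)^2))], ]
  lm <- landmark_set(list("pt'" = corner(c(5, 0, 0)),
                          "al'" = corner(c(5, 10, 0)),
                          "ex'" = corner(c(5, 10, 10)),
                          "ch'" = corner(c(5, 0, 10))),
                     mandible_border = rbind(corner(c(5, 0, 6)),
                                             corner(c(5, 0, 3))))
  patch <- extract_buccal(scan, lm)
  expect_equal(nrow(patch$faces), nrow(scan$faces))
})
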