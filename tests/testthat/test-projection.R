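test_that("extrude_ring sweeps the boundary into a parallel-edged band", {
  patch <- planar_square_patch(side = 20, dist = 30, step = 1)
  ring <- extrude_ring(patch, c(1, 0, 0), half_length = 10)
  # developable sweep: area = perimeter x 2h
  area <- patch_area(ring)
  expect_equal(area, 80 * 20, tolerance = 1e-9)
  # per-vertex decomposition: ring vertex = boundary vertex + s * direction
  n <- nrow(ring$loop)
  s_lo <- ring$vertices[seq_len(n), ] - ring$loop
  s_hi <- ring$vertices[n + seq_len(n), ] - ring$loop
  expect_lt(max(abs(s_lo[, 2:3])), 1e-9)
  expect_lt(max(abs(s_hi[, 2:3])), 1e-9)
  expect_true(all(abs(s_lo[, 1] + 10) < 1e-9))
  expect_true(all(abs(s_hi[, 1] - 10) < 1e-9))
  # exactly two open boundary loops (parallel edges): all open edges sit at
  # s = -h or s = +h
  expect_error(extrude_ring(patch, c(1, 0, 0), half_length = 0),
               "degenerate")
})

test_that("boolean_cut on the baseline scan recovers the original patch", {
  ph <- make_face_series(phantom_spec(resolution = 2, seed = 10))
  fr <- build_frame(ph$lasers$horizontal, ph$lasers$vertical)
  p0 <- extract_buccal(ph$scans$T0, ph$landmarks)
  ring <- extrude_ring(p0, fr$projection_direction, 10)
  cut <- boolean_cut(ring, ph$scans$T0)
  expect_lt(abs(patch_area(cut) - patch_area(p0)) / patch_area(p0), 0.001)
})

test_that("boolean_cut is invariant to translation along the sweep direction", {
  ph <- make_face_series(phantom_spec(resolution = 2, seed = 10))
  fr <- build_frame(ph$lasers$horizontal, ph$lasers$vertical)
  p0 <- extract_buccal(ph$scans$T0, ph$landmarks)
  ring <- extrude_ring(p0, fr$projection_direction, 10)
  moved <- apply_transform(ph$scans$T0,
                           rigid_transform(diag(3), fr$projection_direction))
  cut <- boolean_cut(ring, moved)
  expect_lt(abs(patch_area(cut) - patch_area(p0)) / patch_area(p0), 0.005)
})

test_that("boolean_cut rejects scans displaced beyond the swept band", {
  ph <- make_face_series(phantom_spec(resolution = 2, seed = 10))
  fr <- build_frame(ph$lasers$horizontal, ph$lasers$vertical)
  p0 <- extract_buccal(ph$scans$T0, ph$landmarks)
  ring <- extrude_ring(p0, fr$projection_direction, 10)
  far <- apply_transform(ph$scans$T0,
                         rigid_transform(diag(3), 15 * fr$projection_direction))
  expect_error(boolean_cut(ring, far), "band|intersect")
})

test_that("stv obeys the prism law and vanishes in-plane", {
  fr <- canonical_frame()
  patch <- planar_square_patch(side = 20, dist = 30, step = 1)
  v <- stv(patch, fr)
  expect_equal(v$stv, 12, tolerance = 1e-12)     # 20*20*30 mm^3 = 12 ml
  flat <- planar_square_patch(side = 20, dist = 0, step = 1)
  expect_equal(stv(flat, fr)$stv, 0, tolerance = 1e-12)
})

test_that("stv is additive over face partitions", {
  ph <- make_face_series(phantom_spec(resolution = 3, seed = 12))
  fr <- build_frame(ph$lasers$horizontal, ph$lasers$vertical)
  p0 <- extract_buccal(ph$scans$T0, ph$landmarks)
  whole <- stv(p0, fr)$stv
  nf <- nrow(p0$faces)
  half1 <- buccal_patch(p0$vertices, p0$faces[seq_len(nf %/% 2), ],
                        p0$boundary, side = "right")
  half2 <- buccal_patch(p0$vertices, p0$faces[(nf %/% 2 + 1):nf, ],
                        p0$boundary, side = "right")
  expect_equal(stv(half1, fr)$stv + stv(half2, fr)$stv, whole,
               tolerance = 1e-12)
})

test_that("stv of a spherical-cap patch matches a quadrature oracle", {
  sp <- phantom_spec(resolution = 1, surface = "spherical-cap", seed = 13)
  ph <- make_face_series(sp)
  fr <- build_frame(ph$lasers$horizontal, ph$lasers$vertical)
  p0 <- extract_buccal(ph$scans$T0, ph$landmarks)
  got <- stv(p0, fr)$stv * 1000                      # mm^3
  # oracle: second-order Gauss quadrature of the analytic sphere height over
  # each projected patch triangle
  rc <- sp$curvature_radius
  h_analytic <- function(y, z) sp$apex_x - (rc - sqrt(rc^2 - y^2 - z^2))
  a <- p0$vertices[p0$faces[, 1], 2:3]
  b <- p0$vertices[p0$faces[, 2], 2:3]
  cc <- p0$vertices[p0$faces[, 3], 2:3]
  area2d <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])) / 2
  gauss <- rbind(c(2 / 3, 1 / 6, 1 / 6), c(1 / 6, 2 / 3, 1 / 6),
                 c(1 / 6, 1 / 6, 2 / 3))
  acc <- 0
  for (g in 1:3) {
    py <- gauss[g, 1] * a[, 1] + gauss[g, 2] * b[, 1] + gauss[g, 3] * cc[, 1]
    pz <- gauss[g, 1] * a[, 2] + gauss[g, 2] * b[, 2] + gauss[g, 3] * cc[, 2]
    acc <- acc + h_analytic(py, pz) / 3
  }
  oracle <- sum(acc * area2d)
  expect_lt(abs(got - oracle) / oracle, 0.002)
})

test_that("stv rejects patches crossing the mid-sagittal plane", {
  fr <- canonical_frame()
  crossing <- planar_square_patch(side = 20, dist = 30, step = 1)
  crossing$vertices[, 1] <- crossing$vertices[, 1] - 40   # spans x = 0
  expect_error(stv(crossing, fr), "crosses")
})

test_that("stvc is a signed later-minus-earlier difference", {
  fr <- canonical_frame()
  a <- stv(planar_square_patch(side = 20, dist = 30, label = "T0"), fr)
  b <- stv(planar_square_patch(side = 20, dist = 32, label = "T1"), fr)
  expect_equal(as.numeric(stvc(a, a)), 0)
  expect_equal(as.numeric(stvc(a, b)), 0.8, tolerance = 1e-12)
  expect_equal(as.numeric(stvc(a, b)), -as.numeric(stvc(b, a)))
  expect_equal(attr(stvc(a, b), "period"), "T1-T0")
  bb <- b
  bb$side <- "left"
  expect_error(stvc(a, bb), "side")
})

test_that("a Gaussian bump's projected volume is recovered within 2 percent", {
  A <- 2; sig <- 6
  sp <- phantom_spec(resolution = 1,
                     bumps = list(list(center = c(0, -9), amplitude = A,
                                       sigma = sig, timepoints = "T1")),
                     perturb = list(), seed = 14)
  ph <- make_face_series(sp)
  fr <- build_frame(ph$lasers$horizontal, ph$lasers$vertical)
  p0 <- extract_buccal(ph$scans$T0, ph$landmarks)
  ring <- extrude_ring(p0, fr$projection_direction, 10)
  p1 <- boolean_cut(ring, ph$scans$T1)
  dv <- 1000 * as.numeric(stvc(stv(p0, fr), stv(p1, fr)))
  expect_equal(gaussian_bump_volume(A, sig), 452.3893, tolerance = 1e-4)
  expect_lt(abs(dv - gaussian_bump_volume(A, sig)) /
              gaussian_bump_volume(A, sig), 0.02)
})
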