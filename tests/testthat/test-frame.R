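test_that("laser_origin finds exact and skew intersections", {
  h <- laser_trace(cbind(seq(-5, 5), 0, 0), "horizontal-complete")
  v <- laser_trace(cbind(0, 0, seq(-5, 5)), "vertical")
  expect_equal(laser_origin(h, v), c(0, 0, 0), tolerance = 1e-12)

  # skew lines: x-axis and a z-direction line through (0, 0.4, 0); the
  # common perpendicular is the y-axis, midpoint (0, 0.2, 0)
  v2 <- laser_trace(cbind(0, 0.4, seq(-5, 5)), "vertical")
  expect_equal(laser_origin(h, v2), c(0, 0.2, 0), tolerance = 1e-12)

  # parallel traces cannot cross
  v3 <- laser_trace(cbind(seq(-5, 5), 3, 0), "vertical")
  expect_error(laser_origin(h, v3), "parallel")
  # far-apart skew traces are rejected
  v4 <- laser_trace(cbind(0, 5, seq(-5, 5)), "vertical")
  expect_error(laser_origin(h, v4), "do not cross")
})

test_that("build_frame recovers the canonical mid-sagittal geometry", {
  fr <- canonical_frame()
  expect_equal(abs(fr$projection_direction), c(1, 0, 0), tolerance = 1e-9)
  # sign convention: toward the subject's right = +x (trace ordered left to
  # right along +x)
  expect_equal(fr$projection_direction, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$vertical_axis, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$origin[1], 0, tolerance = 1e-9)
  # origin lies on both planes
  expect_lt(abs(plane_signed_distance(fr$origin, fr$horizontal_plane)), 1e-9)
  expect_lt(abs(plane_signed_distance(fr$origin, fr$midsagittal_plane)), 1e-9)
  # projection direction is orthogonal to the vertical axis
  expect_lt(abs(sum(fr$projection_direction * fr$vertical_axis)), 1e-9)
})

test_that("build_frame is equivariant under rigid motions", {
  hx <- seq(-30, 30, by = 2)
  horiz <- laser_trace(cbind(hx, 60 - 0.004 * hx^2, 0), "horizontal-complete")
  vz <- seq(-30, 30, by = 2)
  c0 <- 60 - 0.004 * mean(hx^2) + 0.002 * mean(vz^2)
  vert <- laser_trace(cbind(0, c0 + 0.3 * vz - 0.002 * vz^2, vz), "vertical")
  f0 <- build_frame(horiz, vert)
  for (seed in 1:5) {
    set.seed(seed)
    tf <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 5, 40)),
                          rnorm(3, sd = 15))
    f1 <- build_frame(apply_transform(horiz, tf), apply_transform(vert, tf))
    expect_lt(max(abs(f1$origin - apply_transform(rbind(f0$origin), tf))),
              1e-9)
    R <- tf$rotation
    expect_lt(max(abs(f1$projection_direction -
                        as.numeric(R %*% f0$projection_direction))), 1e-9)
    expect_lt(max(abs(f1$vertical_axis -
                        as.numeric(R %*% f0$vertical_axis))), 1e-9)
  }
})

test_that("mid-sagittal plane contains origin, Line 1 and Line 2", {
  fr <- canonical_frame()
  n2 <- fr$midsagittal_plane$normal
  expect_lt(abs(sum(n2 * fr$vertical_axis)), 1e-9)    # contains Line 1
  # Line 2 was built inside the x = 0 plane, so its direction is orthogonal
  # to the mid-sagittal normal
  expect_lt(abs(n2[2]), 1e-9)
  expect_lt(abs(n2[3]), 1e-9)
})

test_that("degenerate vertical trace coplanar with the horizontal plane errors", {
  hx <- seq(-30, 30, by = 2)
  horiz <- laser_trace(cbind(hx, 60 - 0.004 * hx^2, 0), "horizontal-complete")
  # vertical trace lying in the z = 0 plane through the origin region
  vert <- laser_trace(cbind(0, seq(30, 90, by = 2), 0), "vertical")
  expect_error(build_frame(horiz, vert), "parallel|degenerate")
})

test_that("frame construction refuses the reflected horizontal laser", {
  hx <- seq(-30, 30, by = 2)
  refl <- laser_trace(cbind(hx, 60 - 0.01 * hx^2, 0), "horizontal-reflected")
  vert <- laser_trace(cbind(0, 60 + 0.3 * seq(-30, 30, 2), seq(-30, 30, 2)),
                      "vertical")
  expect_error(build_frame(refl, vert), "complete")
})
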