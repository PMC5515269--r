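test_that("designed width profile produces an exactly linear velocity ramp", {
  geom <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 3)

  w_fun <- attr(geom, "w_fun")
  # width grows by the velocity ratio across the expansion
  expect_equal(w_fun(-8.99), 3 * w_fun(-1.49))

  # midpoint of the ramp: v = 2/3 of the start speed, w = 1.5x start width
  v <- centerline_velocity(geom, c(-1.49, -5.24, -8.99))
  expect_equal(v[2] / v[1], 2 / 3, tolerance = 1e-12)
  expect_equal(w_fun(-5.24) / w_fun(-1.49), 1.5, tolerance = 1e-12)
  expect_equal(v[1] / v[3], 3, tolerance = 1e-12)

  # the centerline velocity is linear in x to machine precision everywhere
  # inside the expansion
  xs <- seq(-1.49, -8.99, length.out = 57)
  fit <- lm(centerline_velocity(geom, xs) ~ xs)
  expect_lt(max(abs(residuals(fit))) / mean(centerline_velocity(geom, xs)),
            1e-12)

  # ratio 1 is a straight channel
  straight <- design_width_profile(velocity_ratio = 1)
  expect_equal(diff(range(straight$w)), 0)
})

test_that("centerline velocity converts volumetric flux correctly", {
  geom <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 1,
                               w_start = 1.0)
  # 0.2 ml/h through 1 mm x 0.98 mm: 5.556e-2 mm^3/s / 0.98 mm^2
  expect_equal(centerline_velocity(geom, -5), 5.66893e-2, tolerance = 1e-6)

  # doubling the width at fixed flux halves the speed
  wide <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 1,
                               w_start = 2.0)
  expect_equal(centerline_velocity(wide, -5),
               centerline_velocity(geom, -5) / 2)
})

test_that("invalid geometry parameters raise classed errors", {
  expect_error(design_width_profile(q_per_inlet = -1),
               class = "bff_invalid_parameter")
  expect_error(design_width_profile(depth = 0),
               class = "bff_invalid_parameter")
  expect_error(design_width_profile(velocity_ratio = 0.5),
               class = "bff_invalid_parameter")
  expect_error(design_width_profile(x_start = -9, x_end = -1),
               class = "bff_invalid_parameter")
  geom <- design_width_profile()
  expect_error(centerline_velocity(geom, 5), class = "bff_range_error")
  expect_error(centerline_velocity(geom, -99), class = "bff_range_error")
})

test_that("depth-averaged solver conserves flux and matches 1-D mass conservation", {
  # uniform-flow limit: straight channel
  straight <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 1)
  fs <- solve_depth_averaged(straight, 0.05)
  cps <- centerline_profile(fs)
  oneD <- centerline_velocity(straight, cps$x)
  expect_lt(max(abs(cps$speed - oneD) / oneD), 0.02)

  # ratio-3 hyperbolic expansion
  geom <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 3)
  f <- solve_depth_averaged(geom)
  cp <- centerline_profile(f)
  inside <- cp[cp$x <= -1.49 & cp$x >= -8.99, ]
  v_start <- inside$speed[which.min(abs(inside$x + 1.49))]
  v_end <- inside$speed[which.min(abs(inside$x + 8.99))]
  expect_equal(v_start / v_end, 3, tolerance = 0.05)
  expect_gte(summary(lm(speed ~ x, data = inside))$r.squared, 0.99)

  # 2-D centerline within 5% of the 1-D formula throughout the expansion
  oneD <- centerline_velocity(geom, inside$x)
  expect_lt(max(abs(inside$speed - oneD) / oneD), 0.05)

  # cross-sectional volumetric flux conserved within 1% at every section
  fl <- cross_section_flux(f)
  expect_lt(max(abs(fl$flux_mm3_s - attr(f, "q_total"))) / attr(f, "q_total"),
            0.01)

  # all speeds non-negative
  expect_true(all(f$speed >= 0))
})

test_that("the flow field is linear in the flow rate", {
  base <- solve_depth_averaged(design_width_profile(q_per_inlet = 0.1),
                               0.05)
  for (k in c(5, 15, 40)) { # 0.5, 1.5, 4.0 ml/h per inlet
    scaled <- solve_depth_averaged(
      design_width_profile(q_per_inlet = 0.1 * k), 0.05)
    expect_equal(scaled$speed, k * base$speed, tolerance = 1e-9)
  }
})

test_that("halving the grid spacing changes the centerline profile by under 1% on average", {
  geom <- design_width_profile(q_per_inlet = 0.1, velocity_ratio = 3)
  cp1 <- centerline_profile(solve_depth_averaged(geom, 0.025))
  cp2 <- centerline_profile(solve_depth_averaged(geom, 0.0125))
  xs <- cp1$x[cp1$x <= -1.6 & cp1$x >= -8.9]
  a <- approx(cp1$x, cp1$speed, xs)$y
  b <- approx(cp2$x, cp2$speed, xs)$y
  expect_lt(mean(abs(b - a) / a), 0.01)
  expect_lt(max(abs(b - a) / a), 0.03)
})

test_that("a grid too coarse for the narrowest width is rejected", {
  geom <- design_width_profile(w_start = 0.5)
  expect_error(solve_depth_averaged(geom, grid_resolution = 0.2),
               class = "bff_invalid_parameter")
})
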