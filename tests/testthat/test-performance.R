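scene <- scene_geometry()

test_that("radial error is the planar Euclidean distance", {
  expect_identical(radial_error(0, 0), 0)
  expect_identical(radial_error(30, 40), 50)
  expect_identical(radial_error(-12.5, 0), 12.5)
})

test_that("radial error is rotation-invariant about the hole centre", {
  set.seed(3)
  x <- stats::rnorm(50, 20, 40)
  z <- stats::rnorm(50, -10, 40)
  r0 <- radial_error(x, z)
  for (th in stats::runif(100, 0, 2 * pi)) {
    xr <- x * cos(th) - z * sin(th)
    zr <- x * sin(th) + z * cos(th)
    expect_equal(radial_error(xr, zr), r0, tolerance = 1e-9)
  }
})

test_that("the confidence ellipse is scale-equivariant and near-isotropic for isotropic data", {
  set.seed(8)
  xy <- cbind(stats::rnorm(500), stats::rnorm(500))
  e1 <- confidence_ellipse(xy)
  e2 <- confidence_ellipse(2 * xy)
  expect_equal(e2$semi_axes, 2 * e1$semi_axes, tolerance = 1e-12)
  expect_lt(e1$semi_axes[1] / e1$semi_axes[2], 1.1)
})

test_that("degenerate landing clouds are rejected", {
  xy <- cbind(1:10, 2 * (1:10))  # rank-1 covariance
  expect_error(confidence_ellipse(xy), "degenerate")
  expect_error(confidence_ellipse(cbind(1:2, 2:3)), "at least 3")
})

test_that("the ellipse covers the true mean at the nominal rate", {
  set.seed(99)
  hits <- replicate(300, {
    xy <- cbind(stats::rnorm(40, 5, 10), stats::rnorm(40, -3, 6))
    ellipse_contains(confidence_ellipse(xy), c(5, -3))
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.035)
})

test_that("ellipse area shrinks roughly as 1/n", {
  set.seed(12)
  area <- function(n) {
    a <- replicate(200, {
      e <- confidence_ellipse(cbind(stats::rnorm(n, 0, 8), stats::rnorm(n, 0, 8)))
      pi * prod(e$semi_axes)
    })
    mean(a)
  }
  a40 <- area(40)
  a160 <- area(160)
  expect_equal(a40 / a160, 4, tolerance = 0.8)
})

test_that("downswing kinematics match closed forms on a sinusoidal stroke", {
  A <- 0.2
  f <- 1.25
  t <- seq(0, 4, by = 1 / 90)
  ser <- sampled_series(t, A * sin(2 * pi * f * t), 90)
  acc <- finite_difference(moving_average_5pt(ser), 2)$values[, 1]
  idx <- t >= 0.4 & t <= 0.4 + 2 / f
  expect_equal(mean(abs(acc[idx])), A * (2 * pi * f)^2 * 2 / pi,
               tolerance = 0.02 * A * (2 * pi * f)^2 * 2 / pi)
})

test_that("contact speed and lateral acceleration come from the generator truth", {
  scen <- scenario_config("control", club_noise_sd_m = 0, contact_speed_mps = 1.8)
  truth <- plan_trial_truth(scen, qe_total_ms = 500)
  club <- generate_club_trace(scene, scen, truth, rng_seed = 3)
  ev <- detect_swing_events(club, scene)
  k <- kinematic_summary(club, ev, scene)
  expect_equal(k$contact_speed, 1.8, tolerance = 0.018)
  expect_lt(k$accel_z_mean, 1e-8)
  expect_gt(k$accel_x_mean, 0)
})

test_that("kinematics are invariant to world-frame translation", {
  scen <- scenario_config("control", club_noise_sd_m = 0)
  truth <- plan_trial_truth(scen, qe_total_ms = 500)
  club <- generate_club_trace(scene, scen, truth, rng_seed = 4)
  ev <- detect_swing_events(club, scene)
  k0 <- kinematic_summary(club, ev, scene)
  shifted <- club
  shifted$x <- shifted$x + 5
  shifted$y <- shifted$y - 2
  shifted$z <- shifted$z + 1
  sc2 <- scene_geometry(scene$ball_position + c(5, -2, 1),
                        scene$hole_position + c(5, -2, 1))
  ev2 <- detect_swing_events(shifted, sc2)
  k2 <- kinematic_summary(shifted, ev2, sc2)
  expect_equal(k2$contact_speed, k0$contact_speed, tolerance = 1e-9)
  expect_equal(k2$accel_x_mean, k0$accel_x_mean, tolerance = 1e-9)
})

test_that("kinematics require usable swing events", {
  missing <- structure(list(status = "missing"), class = "trial_events")
  expect_error(kinematic_summary(data.frame(t_s = 1:3, x = 1:3, y = 1:3, z = 1:3),
                                 missing, scene), "usable")
})
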