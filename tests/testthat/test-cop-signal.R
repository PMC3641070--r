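test_that("magnitude series is the per-step Euclidean displacement", {
  traj <- cop_trajectory(data.frame(x = c(0, 3), y = c(0, 4)), sample_rate = 100)
  expect_equal(magnitude_series(traj)$magnitude, 5)

  const <- cop_trajectory(data.frame(x = rep(2, 5), y = rep(-1, 5)),
                          sample_rate = 100)
  expect_equal(magnitude_series(const)$magnitude, rep(0, 4))

  traj <- random_walk_traj(100, seed = 42)
  expect_equal(magnitude_series(traj)$magnitude,
               oracle_step_lengths(traj$x, traj$y))
  expect_equal(nrow(magnitude_series(traj)), nrow(traj) - 1)
})

test_that("magnitude series is invariant under rigid motion", {
  traj <- random_walk_traj(200, seed = 7)
  moved <- transform_traj(traj, angle = pi / 5, dx = 13.7, dy = -4.2)
  expect_equal(magnitude_series(moved)$magnitude,
               magnitude_series(traj)$magnitude)
})

test_that("trajectories shorter than 2 samples are rejected", {
  expect_error(cop_trajectory(data.frame(x = 1, y = 1), sample_rate = 100),
               class = "emddfa_invalid_input")
  expect_error(cop_trajectory(data.frame(x = c(1, NA), y = c(1, 2)),
                              sample_rate = 100),
               class = "emddfa_invalid_input")
  expect_error(cop_trajectory(data.frame(x = 1:3, y = 1:3), sample_rate = 0),
               class = "emddfa_invalid_input")
})

test_that("cumulative profile integrates the mean-removed series", {
  expect_equal(cumulative_profile(c(1, 2, 3)), c(-1, -1, 0))
  expect_equal(cumulative_profile(rep(3.5, 10)), rep(0, 10))

  d <- withr::with_seed(11, stats::runif(1000))
  expect_equal(cumulative_profile(d), oracle_profile(d))
  # profile ends at zero within floating tolerance
  expect_lt(abs(cumulative_profile(d)[1000]), 1e-9 * 1000 * max(abs(d)))
  expect_error(cumulative_profile(numeric(0)), class = "emddfa_invalid_input")
})

test_that("COP speed is path length over elapsed duration", {
  # 21 points, unit steps, 1 Hz: 20 mm over 20 s
  traj <- cop_trajectory(data.frame(x = 0:20, y = rep(0, 21)), sample_rate = 1)
  expect_equal(cop_speed(traj), 1.0)

  still <- cop_trajectory(data.frame(x = rep(1, 10), y = rep(2, 10)),
                          sample_rate = 10)
  expect_equal(cop_speed(still), 0)

  traj <- random_walk_traj(500, seed = 3, sample_rate = 100)
  expect_equal(cop_speed(traj),
               sum(oracle_step_lengths(traj$x, traj$y)) / (499 / 100))
  # speed scales linearly with uniform spatial scaling
  expect_equal(cop_speed(transform_traj(traj, scale = 2.5)),
               2.5 * cop_speed(traj))
})

test_that("95% ellipse area matches the chi-square closed form", {
  line <- cop_trajectory(data.frame(x = 1:50, y = 2 * (1:50) + 1),
                         sample_rate = 100)
  expect_warning(a <- cop_area_95(line), class = "emddfa_degenerate_ellipse")
  expect_equal(a, 0)

  # isotropic unit-variance cloud: area -> pi * qchisq(.95, 2)
  cloud <- withr::with_seed(1, data.frame(x = stats::rnorm(1e5),
                                          y = stats::rnorm(1e5)))
  a <- cop_area_95(cop_trajectory(cloud, sample_rate = 100))
  expect_lt(abs(a - pi * stats::qchisq(0.95, 2)) / (pi * stats::qchisq(0.95, 2)),
            0.02)
})

test_that("ellipse area is rigid-motion invariant and scales quadratically", {
  traj <- random_walk_traj(400, seed = 9)
  a0 <- cop_area_95(traj)
  a1 <- cop_area_95(transform_traj(traj, angle = pi / 6, dx = 100, dy = -50))
  expect_lt(abs(a1 - a0) / a0, 1e-9)
  expect_equal(cop_area_95(transform_traj(traj, scale = 3)), 9 * a0,
               tolerance = 1e-9)
})

test_that("sway_metrics returns one tidy row", {
  m <- sway_metrics(random_walk_traj(100, seed = 5))
  expect_s3_class(m, "tbl_df")
  expect_named(m, c("speed", "area"))
  expect_true(all(m >= 0))
})
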