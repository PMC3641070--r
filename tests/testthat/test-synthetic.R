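test_that("fGn has the closed-form lag-1 autocorrelation", {
  ac1 <- function(v) stats::cor(v[-1], v[-length(v)])
  # H = 0.5 is white noise
  expect_lt(abs(ac1(generate_fgn(2^14, 0.5, seed = 1))), 0.03)
  # H = 0.7: gamma(1) = 2^(2H-1) - 1
  a <- mean(sapply(1:10, function(s) ac1(generate_fgn(2^14, 0.7, s))))
  expect_lt(abs(a - (2^0.4 - 1)), 0.03)
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_fgn(4096, 0.7, seed = 9),
                   generate_fgn(4096, 0.7, seed = 9))
  expect_identical(generate_composite(4096, 1, 0.5, 64, seed = 9),
                   generate_composite(4096, 1, 0.5, 64, seed = 9))
  expect_identical(generate_cop2d(n = 1024, seed = 9),
                   generate_cop2d(n = 1024, seed = 9))
  expect_false(identical(generate_fgn(4096, 0.7, seed = 9),
                         generate_fgn(4096, 0.7, seed = 10)))
  # generators do not disturb the caller's RNG stream
  withr::with_seed(1, {
    a <- stats::rnorm(1)
    invisible(generate_fgn(512, 0.6, seed = 4))
    b <- stats::rnorm(1)
  })
  withr::with_seed(1, {
    stats::rnorm(1)
    b_ref <- stats::rnorm(1)
  })
  expect_identical(b, b_ref)
})

test_that("fGn parameters are validated and variance is near unit", {
  expect_error(generate_fgn(1024, 0, seed = 1), class = "emddfa_invalid_input")
  expect_error(generate_fgn(1024, 1, seed = 1), class = "emddfa_invalid_input")
  v <- mean(sapply(1:5, function(s) stats::var(generate_fgn(2^13, 0.6, s))))
  expect_equal(v, 1, tolerance = 0.1)
})

test_that("round trip: DFA recovers the generating Hurst index", {
  for (H in c(0.3, 0.7)) {
    a <- mean(sapply(1:5, function(s) dfa(generate_fgn(2^13, H, s))$alpha))
    expect_lt(abs(a - H), 0.07)
  }
  # fBm: alpha = H + 1
  a <- mean(sapply(1:5, function(s) dfa(generate_fbm(2^13, 0.3, s))$alpha))
  expect_lt(abs(a - 1.3), 0.1)
})

test_that("composite crossover scale must be interior", {
  expect_error(generate_composite(4096, 1, 0.5, 4, seed = 1),
               class = "emddfa_invalid_input")
  expect_error(generate_composite(4096, 1, 0.5, 1000, seed = 1),
               class = "emddfa_invalid_input")
})

test_that("equal-exponent composites are indistinguishable from monofractal", {
  # the two-segment fit has an intrinsic slope-difference noise floor, so
  # compare the composite's apparent regime gap against genuine fGn of the
  # same exponent on paired seeds
  gap <- function(x) {
    fit <- fit_crossover(dfa(x)$curve)
    abs(fit$alpha_short - fit$alpha_long)
  }
  g_comp <- sapply(1:8, function(s)
    gap(generate_composite(2^13, 0.8, 0.8, 64, s)))
  g_mono <- sapply(1:8, function(s) gap(generate_fgn(2^13, 0.8, s)))
  # no MORE apparent regime structure than a genuine monofractal
  expect_lt(mean(g_comp), mean(g_mono) + 0.1)
})

test_that("COP simulator produces plausible finite trajectories", {
  traj <- generate_cop2d(n = 2048, sample_rate = 100, seed = 3)
  expect_s3_class(traj, "cop_trajectory")
  mag <- magnitude_series(traj)
  expect_equal(nrow(mag), 2047)
  expect_true(all(is.finite(mag$magnitude)))
  expect_true(all(mag$magnitude >= 0))
  rms <- function(v) sqrt(mean((v - mean(v))^2))
  expect_gt(rms(traj$x), 1); expect_lt(rms(traj$x), 10)
  # ground truth is carried in metadata
  expect_equal(attr(traj, "meta")$alpha_fast, 1.1)
})

test_that("slow drift inflates the sway area", {
  a0 <- cop_area_95(generate_cop2d(n = 2048, sample_rate = 100,
                                   drift_mm = 0, seed = 11))
  a1 <- cop_area_95(generate_cop2d(n = 2048, sample_rate = 100,
                                   drift_mm = 10, seed = 11))
  expect_gt(a1, a0)
})

test_that("spectral exponent tracks the fluctuation exponent (beta = 2 alpha - 1)", {
  # white noise: flat spectrum
  b <- mean(sapply(1:10, function(s)
    spectral_exponent(generate_fgn(2^14, 0.5, s))$beta))
  expect_lt(abs(b), 0.1)
  # fGn H = 0.7: beta = 2H - 1 = 0.4
  b <- mean(sapply(1:10, function(s)
    spectral_exponent(generate_fgn(2^14, 0.7, s))$beta))
  expect_lt(abs(b - 0.4), 0.15)
  # Brownian path: alpha = 1.5 so beta = 2
  b <- mean(sapply(1:10, function(s)
    spectral_exponent(cumsum(generate_fgn(2^14, 0.5, s + 40)))$beta))
  expect_lt(abs(b - 2), 0.2)
  expect_error(spectral_exponent(stats::rnorm(128)),
               class = "emddfa_invalid_input")
})
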