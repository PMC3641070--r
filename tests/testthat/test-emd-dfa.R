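make_sine_decomposition <- function(period = 20, n_periods = 10) {
  n <- period * n_periods
  s <- sin(2 * pi * seq_len(n) / period)
  dec <- emd(s, max_imfs = 1)
  dec
}

test_that("intrinsic scales are inter-minima distances, residual excluded", {
  dec <- make_sine_decomposition(period = 20)
  tab <- intrinsic_scales(dec)
  expect_equal(unique(unlist(tab$per_imf[[1]])), 20L)
  expect_equal(tab$scales, 20L)

  # broadband decomposition: equality with brute-force per-IMF scan
  dec <- emd(cumulative_profile(withr::with_seed(5, stats::rnorm(2048))))
  tab <- intrinsic_scales(dec)
  for (j in seq_len(ncol(dec$imfs))) {
    expect_equal(tab$per_imf[[j]], oracle_interminima(dec$imfs[, j]))
  }
  expect_equal(tab$scales, sort(unique(unlist(tab$per_imf))))
  # counts add up over IMFs
  expect_equal(sum(tab$counts), length(unlist(tab$per_imf)))
})

test_that("degenerate decompositions yield a no-scales error", {
  # monotone input: no IMF at all
  x <- seq_len(64) + 0.001 * seq_len(64)^2
  dec <- emd(x)
  expect_equal(ncol(dec$imfs), 0)
  expect_error(intrinsic_scales(dec), class = "emddfa_no_scales")
})

test_that("per-scale reconstruction keeps exactly the matching segments", {
  dec <- make_sine_decomposition(period = 20)
  tab <- intrinsic_scales(dec)
  rec <- reconstruct_at_scale(dec, tab, 20)
  span <- range(find_extrema(dec$imfs[, 1])$minima)
  # within the minima span the IMF is reproduced exactly, nothing else kept
  expect_equal(rec$y[span[1]:(span[2] - 1)],
               dec$imfs[span[1]:(span[2] - 1), 1])
  expect_true(all(rec$y[!rec$mask] == 0))
  expect_error(reconstruct_at_scale(dec, tab, 7),
               class = "emddfa_invalid_scale")
})

test_that("retained masks match a brute-force segment scan and partition", {
  dec <- emd(cumulative_profile(withr::with_seed(6, stats::rnorm(1024))))
  tab <- intrinsic_scales(dec)
  # union over IMFs at each scale, against the per-IMF oracle
  for (s in tab$scales[c(1, length(tab$scales) %/% 2, length(tab$scales))]) {
    rec <- reconstruct_at_scale(dec, tab, s)
    oracle_mask <- Reduce(`|`, lapply(seq_len(ncol(dec$imfs)), function(j)
      oracle_mask_one_imf(dec$imfs[, j], s)))
    expect_equal(rec$mask, oracle_mask)
  }
  # per IMF, scale-specific masks partition the samples between the
  # first and last minima: each covered exactly once
  for (j in seq_len(ncol(dec$imfs))) {
    cover <- rowSums(vapply(tab$scales, function(s)
      oracle_mask_one_imf(dec$imfs[, j], s), logical(nrow(dec$imfs))))
    mins <- find_extrema(dec$imfs[, j])$minima
    if (length(mins) < 2) next
    inside <- mins[1]:(mins[length(mins)] - 1)
    expect_true(all(cover[inside] == 1))
    expect_true(all(cover[-inside] == 0))
  }
})

test_that("fluctuation function normalizations follow their definitions", {
  expect_equal(fluctuation_function(c(3, 0, 0, 0), rep(TRUE, 4), "full"), 1.5)
  expect_equal(
    fluctuation_function(c(3, 0, 0, 0), c(TRUE, FALSE, FALSE, FALSE),
                         "retained"), 3)
  y <- withr::with_seed(2, stats::rnorm(100))
  mask <- withr::with_seed(3, stats::runif(100) < 0.4)
  y[!mask] <- 0
  for (mode in c("full", "retained")) {
    expect_equal(fluctuation_function(y, mask, mode),
                 oracle_fluct(y, mask, mode))
  }
  expect_error(fluctuation_function(y, rep(FALSE, 100)),
               class = "emddfa_empty_scale")
})

test_that("crossover fit recovers exact piecewise power laws", {
  # single power law: both slopes equal, no distinct regimes
  s <- 10^seq(0.5, 3, length.out = 20)
  curve <- tibble::tibble(scale = s, fluctuation = s^0.5)
  fit <- fit_crossover(curve)
  expect_equal(fit$alpha_short, 0.5, tolerance = 1e-10)
  expect_equal(fit$alpha_long, 0.5, tolerance = 1e-10)
  expect_false(fit$distinct_regimes)

  # continuous two-regime curve: slopes 1.0 then 0.5, break at s = 10
  s1 <- 10^seq(0, 1, length.out = 12)
  s2 <- 10^seq(1.1, 2.5, length.out = 12)
  f <- c(s1^1.0, 10^0.5 * s2^0.5)
  fit <- fit_crossover(tibble::tibble(scale = c(s1, s2), fluctuation = f))
  expect_equal(fit$alpha_short, 1.0, tolerance = 1e-6)
  expect_equal(fit$alpha_long, 0.5, tolerance = 1e-6)
  expect_gte(fit$crossover_scale, 8)
  expect_lte(fit$crossover_scale, 13)
  expect_true(fit$distinct_regimes)

  # same curve with log-domain noise: slopes within 0.05
  withr::with_seed(4, {
    fn <- 10^(log10(f) + stats::rnorm(24, sd = 0.01))
    fit <- fit_crossover(tibble::tibble(scale = c(s1, s2), fluctuation = fn))
    expect_equal(fit$alpha_short, 1.0, tolerance = 0.05)
    expect_equal(fit$alpha_long, 0.5, tolerance = 0.05)
  })
})

test_that("crossover fit falls back to a single slope on short curves", {
  s <- 10^seq(0, 2, length.out = 5)
  fit <- fit_crossover(tibble::tibble(scale = s, fluctuation = s^0.7))
  expect_true(fit$single_regime_fallback)
  expect_equal(fit$alpha_short, fit$alpha_long)
  expect_equal(fit$alpha_short, 0.7, tolerance = 1e-10)
  expect_true(is.na(fit$crossover_scale))
})

test_that("breakpoint ties resolve to the smaller index", {
  # perfectly linear curve: every breakpoint gives sse ~ 0; the first
  # admissible one must be chosen
  s <- 10^seq(0, 2, length.out = 10)
  fit <- fit_crossover(tibble::tibble(scale = s, fluctuation = s))
  expect_equal(fit$breakpoint, 3L)
})

test_that("the pipeline rejects short series and is deterministic", {
  expect_error(emd_dfa(stats::rnorm(100)), class = "emddfa_invalid_input")
  x <- generate_fgn(1024, 0.6, seed = 21)
  r1 <- emd_dfa(x, sample_rate = 1000)
  r2 <- emd_dfa(x, sample_rate = 1000)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$curve, r2$curve)
})

test_that("white-noise input gives a global exponent near one half", {
  g <- sapply(1:10, function(s) emd_dfa(generate_fgn(2^12, 0.5, s))$alpha_global)
  expect_gt(mean(g), 0.4)
  expect_lt(mean(g), 0.6)
})

test_that("crossover is reported in both samples and milliseconds", {
  x <- generate_composite(2^13, 1, 0.4, 50, seed = 2)
  g <- glance(emd_dfa(x, sample_rate = 1000))
  expect_equal(g$crossover_ms, g$crossover_scale)  # 1000 Hz: 1 sample = 1 ms
  g2 <- glance(emd_dfa(x, sample_rate = 100))
  expect_equal(g2$crossover_ms, g2$crossover_scale * 10)
})

test_that("scale curve respects the analyzed band and bins are populated", {
  x <- generate_fgn(4096, 0.5, seed = 31)
  r <- emd_dfa(x)
  expect_true(all(r$curve$scale >= 4 - 1e-9))
  expect_true(all(r$curve$scale <= 4096 / 8 + 1e-9))
  expect_true(all(r$curve$fluctuation > 0))
  expect_true(all(diff(r$curve$scale) > 0))
  # every interior bin holds at least the configured number of segments
  expect_true(all(utils::head(r$curve$n_segments, -1) >= 10))
})
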