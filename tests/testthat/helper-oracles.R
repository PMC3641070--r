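# Independent brute-force oracles used to pin down the vectorized
# implementations on small instances. These deliberately use plain loops.

# Euclidean step lengths, one explicit loop iteration per step
oracle_step_lengths <- function(x, y) {
  out <- numeric(length(x) - 1)
  for (i in seq_len(length(x) - 1)) {
    out[i] <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  out
}

# Running-sum cumulative profile
oracle_profile <- function(d) {
  m <- mean(d)
  acc <- 0
  out <- numeric(length(d))
  for (i in seq_along(d)) {
    acc <- acc + (d[i] - m)
    out[i] <- acc
  }
  out
}

# Inter-minima distances of one series by scanning consecutive minima pairs
oracle_interminima <- function(v) {
  mins <- find_extrema(v)$minima
  if (length(mins) < 2) return(integer(0))
  out <- integer(length(mins) - 1)
  for (j in seq_len(length(mins) - 1)) out[j] <- mins[j + 1] - mins[j]
  out
}

# Retained mask for one IMF at scale s by explicit segment scan
oracle_mask_one_imf <- function(v, s) {
  mask <- logical(length(v))
  mins <- find_extrema(v)$minima
  if (length(mins) < 2) return(mask)
  for (j in seq_len(length(mins) - 1)) {
    if (mins[j + 1] - mins[j] == s) {
      mask[mins[j]:(mins[j + 1] - 1)] <- TRUE
    }
  }
  mask
}

# One-line sum-of-squares fluctuation oracle
oracle_fluct <- function(y, mask, mode) {
  denom <- if (mode == "full") length(y) else sum(mask)
  sqrt(sum(y[mask]^2) / denom)
}

# Naive double-loop DFA fluctuation at one window size (forward + reverse)
oracle_dfa_window <- function(x, w, order = 1) {
  profile <- cumsum(x - mean(x))
  N <- length(profile)
  k <- N %/% w
  sq <- 0
  cnt <- 0
  detrend <- function(seg) {
    t <- seq_along(seg)
    stats::lm(seg ~ stats::poly(t, order, raw = TRUE))$residuals
  }
  for (j in seq_len(k)) {
    seg <- profile[((j - 1) * w + 1):(j * w)]
    r <- detrend(seg)
    sq <- sq + sum(r^2); cnt <- cnt + w
    seg <- profile[(N - j * w + 1):(N - (j - 1) * w)]
    r <- detrend(seg)
    sq <- sq + sum(r^2); cnt <- cnt + w
  }
  sqrt(sq / cnt)
}

# Random-walk trajectory fixture
random_walk_traj <- function(n, seed, sample_rate = 100) {
  withr::with_seed(seed, {
    cop_trajectory(
      data.frame(x = cumsum(stats::rnorm(n)), y = cumsum(stats::rnorm(n))),
      sample_rate = sample_rate)
  })
}

# Rotate + translate a trajectory rigidly
transform_traj <- function(traj, angle = 0, dx = 0, dy = 0, scale = 1) {
  x <- traj$x * scale; y <- traj$y * scale
  cop_trajectory(
    data.frame(x = cos(angle) * x - sin(angle) * y + dx,
               y = sin(angle) * x + cos(angle) * y + dy),
    sample_rate = sample_rate(traj))
}
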