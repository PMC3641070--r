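#' Construct a center-of-pressure trajectory
#'
#' Validates and tags a two-column data frame of mediolateral (`x`) and
#' anteroposterior (`y`) center-of-pressure displacements, in millimetres,
#' sampled at a fixed rate. This is the raw-input container consumed by all
#' sway analyses; no filtering or detrending is applied to it.
#'
#' @param data A data frame with numeric columns `x` and `y` (other columns
#'   are kept but ignored by analyses).
#' @param sample_rate Sampling rate in Hz (positive).
#' @param meta Optional named list of trial annotations (subject id,
#'   eyes-open/closed label, ...).
#' @return A tibble of class `cop_trajectory` with attributes `sample_rate`
#'   and `meta`.
#' @examples
#' traj <- cop_trajectory(data.frame(x = c(0, 3), y = c(0, 4)), sample_rate = 100)
#' @export
cop_trajectory <- function(data, sample_rate, meta = list()) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with columns `x` and `y`.",
          class = "emddfa_invalid_input")
  }
  if (!all(c("x", "y") %in% names(data))) {
    abort("`data` must contain columns `x` and `y`.",
          class = "emddfa_invalid_input")
  }
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  check_numeric(data$x, "x", min_len = 2L)
  check_numeric(data$y, "y", min_len = 2L)
  if (length(data$x) != length(data$y)) {
    abort("`x` and `y` must have equal length.", class = "emddfa_invalid_input")
  }
  out <- tibble::as_tibble(data)
  attr(out, "sample_rate") <- as.numeric(sample_rate)
  attr(out, "meta") <- meta
  class(out) <- c("cop_trajectory", class(out))
  out
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory> %d samples @ %g Hz (%.3g s)\n",
              nrow(x), sample_rate(x), (nrow(x) - 1) / sample_rate(x)))
  NextMethod()
}

#' Sampling rate of a trajectory or magnitude series
#'
#' @param x A `cop_trajectory` or `magnitude_series` object.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(x) {
  sr <- attr(x, "sample_rate")
  if (is.null(sr)) abort("Object carries no sample rate.",
                         class = "emddfa_invalid_input")
  sr
}

#' Displacement-magnitude series of a COP trajectory
#'
#' Reduces the 2-D trajectory to the one-dimensional series of Euclidean
#' displacement lengths between consecutive samples,
#' \eqn{d(i) = \sqrt{(x(i+1)-x(i))^2 + (y(i+1)-y(i))^2}}. This magnitude
#' series -- rather than the raw anteroposterior/mediolateral coordinates --
#' is the signal whose fractal scaling the package quantifies: correlations in
#' the magnitude series capture nonlinear properties of sway dynamics that the
#' raw coordinates can miss.
#'
#' @param traj A [cop_trajectory()].
#' @return A tibble of class `magnitude_series` with columns `step` (1-based
#'   index of the interval) and `magnitude` (mm), one row per consecutive
#'   sample pair (length `nrow(traj) - 1`), carrying the `sample_rate`
#'   attribute.
#' @examples
#' traj <- cop_trajectory(data.frame(x = c(0, 3), y = c(0, 4)), sample_rate = 100)
#' magnitude_series(traj)$magnitude  # 5
#' @export
magnitude_series <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  out <- tibble::tibble(step = seq_along(d), magnitude = d)
  attr(out, "sample_rate") <- sample_rate(traj)
  class(out) <- c("magnitude_series", class(out))
  out
}

# Internal: accept a magnitude_series tibble or bare numeric vector
as_series <- function(x, name = "x") {
  if (inherits(x, "magnitude_series")) return(x$magnitude)
  if (is.data.frame(x) && "magnitude" %in% names(x)) return(x$magnitude)
  check_numeric(x, name, min_len = 1L)
  as.numeric(x)
}

#' Mean-removed cumulative profile of a series
#'
#' Integrates the mean-removed series:
#' \eqn{Y(k) = \sum_{i \le k} (d(i) - \bar d)}. The profile is the random-walk
#' representation on which both the EMD-based and conventional detrended
#' fluctuation analyses operate; by construction its final element is zero up
#' to floating-point rounding.
#'
#' @param series A `magnitude_series` tibble or numeric vector of length >= 2.
#' @return Numeric vector of the same length.
#' @examples
#' cumulative_profile(c(1, 2, 3))  # -1 -1 0
#' @export
cumulative_profile <- function(series) {
  d <- as_series(series, "series")
  check_numeric(d, "series", min_len = 2L)
  cumsum(d - mean(d))
}

#' Average COP speed
#'
#' Total path length of the trajectory divided by trial duration, where the
#' duration is the elapsed time between first and last samples,
#' `(n - 1) / sample_rate`.
#'
#' @param traj A [cop_trajectory()].
#' @return Speed in mm/s (non-negative scalar).
#' @export
cop_speed <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  duration <- (nrow(traj) - 1) / sample_rate(traj)
  if (duration <= 0) abort("Trajectory duration is zero.",
                           class = "emddfa_invalid_input")
  sum(magnitude_series(traj)$magnitude) / duration
}

#' 95% confidence-ellipse sway area
#'
#' Area of the covariance-based confidence ellipse enclosing 95% of the COP
#' point cloud: \eqn{A = \pi \, q \, \sqrt{\det S}} with `S` the unbiased 2x2
#' sample covariance of `(x, y)` and `q` the 0.95 quantile of the chi-square
#' distribution with 2 degrees of freedom (\eqn{q = -2\ln 0.05 \approx 5.99}).
#' The area is invariant under rotation and translation of the trajectory.
#'
#' A degenerate (collinear or constant) point cloud yields area 0 with a
#' warning rather than an error, so batch pipelines are not aborted by a flat
#' trial.
#'
#' @param traj A [cop_trajectory()].
#' @return Area in mm^2.
#' @export
cop_area_95 <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (nrow(traj) < 3) abort("Need at least 3 samples for an ellipse.",
                            class = "emddfa_invalid_input")
  S <- cov(cbind(traj$x, traj$y))
  d <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  scale2 <- max(S[1, 1], S[2, 2], .Machine$double.eps)
  if (d <= .Machine$double.eps * scale2^2 * nrow(traj)) {
    warn("Degenerate (collinear) COP cloud; 95% ellipse area is 0.",
         class = "emddfa_degenerate_ellipse")
    return(0)
  }
  pi * qchisq(0.95, df = 2) * sqrt(d)
}

#' Classical posturographic summary metrics
#'
#' @param traj A [cop_trajectory()].
#' @return One-row tibble with `speed` (mm/s) and `area` (mm^2).
#' @examples
#' sway_metrics(generate_cop2d(n = 1000, sample_rate = 100, seed = 1))
#' @export
sway_metrics <- function(traj) {
  tibble::tibble(speed = cop_speed(traj), area = cop_area_95(traj))
}
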