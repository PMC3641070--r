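#' Conventional detrended fluctuation analysis
#'
#' Textbook DFA: the mean-removed series is integrated into a profile; the
#' profile is partitioned into non-overlapping windows of size `n` (from both
#' the start and, to use all samples when `N` is not a multiple of `n`, again
#' from the end); an order-`detrend_order` polynomial trend is removed within
#' each window; and `F(n)` is the RMS of the pooled residuals. The scaling
#' exponent `alpha` is the least-squares slope of `log10 F(n)` versus
#' `log10 n`. For fractional Gaussian noise with Hurst index `H`,
#' `alpha = H`; for fractional Brownian motion, `alpha = H + 1`; white noise
#' gives 0.5 and 1/f (pink) noise 1.
#'
#' @param x Numeric series.
#' @param window_sizes Integer window sizes. Default: 20 sizes log-spaced in
#'   `[4, length(x) / 4]`. Windows with fewer than `detrend_order + 2` samples
#'   are rejected.
#' @param detrend_order Polynomial detrending order (default 1, i.e. DFA-1).
#' @return An object of class `dfa`: a list with `curve` (a tibble with
#'   columns `scale` = window size and `fluctuation`), `alpha`, `intercept`,
#'   `r2` and `detrend_order`. [generics::glance()] returns a one-row tibble,
#'   [generics::tidy()] the curve, and `autoplot()` the log-log plot.
#' @examples
#' glance(dfa(generate_fgn(4096, hurst = 0.7, seed = 1)))$alpha
#' @export
dfa <- function(x, window_sizes = NULL, detrend_order = 1L) {
  check_numeric(x, "x", min_len = 16L)
  if (detrend_order < 0) abort("`detrend_order` must be >= 0.",
                               class = "emddfa_invalid_input")
  N <- length(x)
  if (is.null(window_sizes)) {
    window_sizes <- unique(pmin(N %/% 4L,
                                round(10^seq(log10(4), log10(N / 4),
                                             length.out = 20))))
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  window_sizes <- window_sizes[window_sizes >= detrend_order + 2 &
                                 window_sizes <= N %/% 2]
  if (length(window_sizes) < 2) {
    abort("Need at least 2 admissible window sizes.",
          class = "emddfa_invalid_input")
  }
  if (N < 4L * max(window_sizes)) {
    warn("Series shorter than 4x the largest window; largest scales are noisy.",
         class = "emddfa_short_series")
  }
  profile <- cumsum(x - mean(x))
  f <- vapply(window_sizes, function(w) dfa_window_rms(profile, w, detrend_order),
              numeric(1))
  keep <- is.finite(f) & f > 0
  curve <- tibble::tibble(scale = as.numeric(window_sizes[keep]),
                          fluctuation = f[keep])
  fit <- ols_line(log10(curve$scale), log10(curve$fluctuation))
  structure(
    list(curve = curve, alpha = unname(fit["slope"]),
         intercept = unname(fit["intercept"]), r2 = unname(fit["r2"]),
         detrend_order = as.integer(detrend_order)),
    class = "dfa")
}

# Internal: RMS detrended fluctuation at one window size, pooling windows
# taken from the start and from the end of the profile.
dfa_window_rms <- function(profile, w, order) {
  N <- length(profile)
  k <- N %/% w
  if (k < 1) return(NA_real_)
  X <- outer(seq_len(w), 0:order, `^`)
  qrX <- qr(X)
  fwd <- matrix(profile[seq_len(k * w)], nrow = w)
  rev <- matrix(profile[(N - k * w + 1L):N], nrow = w)
  r1 <- qr.resid(qrX, fwd)
  r2 <- qr.resid(qrX, rev)
  sqrt((sum(r1^2) + sum(r2^2)) / (2 * k * w))
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf("<dfa> order-%d detrending, %d windows: alpha = %.3f (r2 = %.4f)\n",
              x$detrend_order, nrow(x$curve), x$alpha, x$r2))
  invisible(x)
}

#' @rdname dfa
#' @param x A `dfa` object.
#' @param ... Unused.
#' @method tidy dfa
#' @export
tidy.dfa <- function(x, ...) x$curve

#' @rdname dfa
#' @method glance dfa
#' @export
glance.dfa <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, intercept = x$intercept, r2 = x$r2,
                 n_windows = nrow(x$curve), detrend_order = x$detrend_order)
}

#' @rdname autoplot.emd_dfa
#' @method autoplot dfa
#' @export
autoplot.dfa <- function(object, ...) {
  p <- plot_fluctuation(object$curve, NULL, xlab = "window size n (samples)")
  seg <- tibble::tibble(
    segment = "global",
    scale = range(object$curve$scale),
    fluctuation = 10^(object$intercept + object$alpha *
                        log10(range(object$curve$scale))))
  p + ggplot2::geom_line(data = seg,
                         ggplot2::aes(x = .data$scale, y = .data$fluctuation),
                         colour = "red3", linewidth = 0.4)
}
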