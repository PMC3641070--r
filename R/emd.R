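#' Locate the local extrema of a series
#'
#' Strict local extrema are detected by sign change of the first difference.
#' A flat plateau flanked by opposite slopes is reported once, at its midpoint
#' (rounded down). The first and last samples are never reported as extrema.
#'
#' @param x Numeric vector of length >= 3.
#' @return A list with integer vectors `minima` and `maxima` (1-based indices
#'   into `x`, each sorted increasing).
#' @examples
#' find_extrema(c(0, 1, 0, -1, 0))  # maxima 2, minima 4
#' @export
find_extrema <- function(x) {
  check_numeric(x, "x", min_len = 3L)
  s <- sign(diff(x))
  nz <- which(s != 0)
  minima <- integer(0)
  maxima <- integer(0)
  if (length(nz) >= 2) {
    a <- nz[-length(nz)]
    b <- nz[-1]
    turn <- s[a] != s[b]
    a <- a[turn]; b <- b[turn]
    # plateau spans samples (a+1)..b; midpoint rounded down
    mid <- (a + 1L + b) %/% 2L
    is_max <- s[a] > 0
    maxima <- mid[is_max]
    minima <- mid[!is_max]
  }
  list(minima = as.integer(minima), maxima = as.integer(maxima))
}

# Internal: number of local extrema
n_extrema <- function(x) {
  if (length(x) < 3) return(0L)
  e <- find_extrema(x)
  length(e$minima) + length(e$maxima)
}

# Internal: number of zero crossings (sign changes, zeros ignored)
n_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

# Internal: cubic-spline envelope through the given extrema, with 2 extrema
# mirror-extended beyond each end to control boundary swings. Falls back to
# what stats::spline supports when fewer knots exist (line for 2 knots).
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  ext <- min(2L, k - 1L)
  li <- 2 - idx[seq(ext + 1, 2, -1)]          # mirror about sample 1
  lv <- val[seq(ext + 1, 2, -1)]
  ri <- 2L * n - idx[seq(k - 1, k - ext, -1)] # mirror about sample n
  rv <- val[seq(k - 1, k - ext, -1)]
  if (ext < 1) { li <- lv <- ri <- rv <- numeric(0) }
  stats::spline(c(li, idx, ri), c(lv, val, rv), xout = seq_len(n),
                method = "natural")$y
}

# Internal: mean of upper and lower envelopes, or NULL if the series has
# too few extrema (< 3 in total) to be anything but a trend. A side with a
# single extremum gets an endpoint-anchored envelope instead of a mirrored
# spline, so near-trend remainders can still be sifted down to <= 2 extrema.
envelope_mean <- function(x) {
  e <- find_extrema(x)
  if (length(e$maxima) + length(e$minima) < 3) return(NULL)
  n <- length(x)
  one_side <- function(idx) {
    if (length(idx) >= 2) {
      spline_envelope(idx, x[idx], n)
    } else {
      stats::spline(c(1, idx, n), c(x[1], x[idx], x[n]), xout = seq_len(n),
                    method = "natural")$y
    }
  }
  (one_side(e$maxima) + one_side(e$minima)) / 2
}

#' One sifting pass of empirical mode decomposition
#'
#' Subtracts from the series the mean of its upper and lower cubic-spline
#' envelopes (interpolating the maxima and minima respectively, with two
#' extrema mirror-extended past each end). Repeated sifting drives a series
#' toward an intrinsic mode function: locally symmetric oscillation with
#' near-zero envelope mean.
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @return Numeric vector, the candidate intrinsic mode component.
#' @export
sift_once <- function(x) {
  check_numeric(x, "x", min_len = 3L)
  m <- envelope_mean(x)
  if (is.null(m)) {
    abort("Series has too few extrema to sift: trend reached.",
          class = "emddfa_trend_reached")
  }
  x - m
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) and a residual
#' trend by iterative sifting. Each mode is refined until the normalized
#' squared difference between successive sifts (the Cauchy criterion)
#' \eqn{\sum (h_{k-1} - h_k)^2 / \sum h_{k-1}^2} falls below `sd_threshold`
#' while the mode satisfies the IMF defect bound (extrema and zero-crossing
#' counts differing by at most 1), or `max_sift` iterations elapse, or the
#' candidate runs out of extrema. Extraction stops when the remaining
#' residual has fewer than 3 local extrema (monotone or single-hump) or when
#' `max_imfs` modes have been extracted.
#'
#' The decomposition is complete by construction: the IMFs and the residual
#' sum back to the input up to floating-point rounding. A constant input
#' yields zero IMFs with the input as residual. The algorithm is
#' deterministic.
#'
#' @param x Numeric vector of length >= 16.
#' @param max_imfs Maximum number of modes to extract (default 12).
#' @param sd_threshold Cauchy stopping threshold for sifting (default 0.2,
#'   the canonical range being 0.2-0.3).
#' @param max_sift Cap on sifting iterations per mode (default 200).
#' @return An object of class `emd_decomposition`: a list with `imfs` (an
#'   `n x k` matrix, one column per mode, fastest mode first), `residual`
#'   (length-`n` trend), `n_sift` (sift iterations per mode) and
#'   `source_length`. [generics::tidy()] returns the components as a long
#'   tibble; `autoplot()` draws them.
#' @examples
#' t <- seq(0, 4, length.out = 800)
#' dec <- emd(sin(2 * pi * 25 * t) + sin(2 * pi * 2 * t))
#' ncol(dec$imfs)
#' @export
emd <- function(x, max_imfs = 12L, sd_threshold = 0.2, max_sift = 200L) {
  check_numeric(x, "x", min_len = 16L)
  check_scalar(sd_threshold, "sd_threshold", positive = TRUE)
  if (max_imfs < 1) abort("`max_imfs` must be >= 1.", class = "emddfa_invalid_input")
  n <- length(x)
  r <- as.numeric(x)
  imfs <- list()
  n_sift <- integer(0)

  # extrema-vs-zero-crossing defect; 0 or 1 for a proper IMF
  defect <- function(v) {
    abs(n_extrema(v) - n_zero_crossings(v))
  }

  while (length(imfs) < max_imfs && n_extrema(r) >= 3) {
    h <- r
    iter <- 0L
    repeat {
      m <- envelope_mean(h)
      if (is.null(m)) break  # candidate ran out of extrema
      h_new <- h - m
      iter <- iter + 1L
      sd_k <- sum((h - h_new)^2) / sum(h^2)
      h <- h_new
      if (!is.finite(sd_k) || iter >= max_sift) break
      if (sd_k < sd_threshold && defect(h) <= 1) break
    }
    if (iter == 0L) break
    imfs[[length(imfs) + 1L]] <- h
    n_sift <- c(n_sift, iter)
    r <- r - h
  }

  imf_mat <- if (length(imfs)) do.call(cbind, imfs) else
    matrix(numeric(0), nrow = n, ncol = 0)
  colnames(imf_mat) <- if (ncol(imf_mat)) paste0("imf", seq_len(ncol(imf_mat)))
  structure(
    list(imfs = imf_mat, residual = r, n_sift = n_sift, source_length = n,
         sd_threshold = sd_threshold, max_sift = as.integer(max_sift)),
    class = "emd_decomposition"
  )
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMFs + residual, %d samples\n",
              ncol(x$imfs), x$source_length))
  if (length(x$n_sift)) {
    cat("  sift iterations per mode:", paste(x$n_sift, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname emd
#' @param x An `emd_decomposition` object (for `tidy`).
#' @param ... Unused.
#' @method tidy emd_decomposition
#' @export
tidy.emd_decomposition <- function(x, ...) {
  n <- x$source_length
  k <- ncol(x$imfs)
  comp <- c(if (k) colnames(x$imfs), "residual")
  vals <- c(if (k) as.numeric(x$imfs), x$residual)
  tibble::tibble(
    index = rep.int(seq_len(n), k + 1L),
    component = factor(rep(comp, each = n), levels = comp),
    value = vals
  )
}

#' Plot an empirical mode decomposition
#'
#' @param object An `emd_decomposition` object.
#' @param ... Unused.
#' @return A ggplot with one facet per component.
#' @method autoplot emd_decomposition
#' @export
autoplot.emd_decomposition <- function(object, ...) {
  df <- tidy.emd_decomposition(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "sample", y = NULL)
}
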