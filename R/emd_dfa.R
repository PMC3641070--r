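#' Intrinsic time scales of an empirical mode decomposition
#'
#' Extracts, for every intrinsic mode function, the distances (in samples)
#' between neighbouring local minima. These inter-minima distances are the
#' intrinsic scales of the signal: mono-component oscillation periods derived
#' from the data itself rather than from a preset grid, unaffected by the
#' nonstationary trend. The residual mode is always excluded.
#'
#' Within an IMF, the segment associated with a minima pair \eqn{(m_j,
#' m_{j+1})} covers samples \eqn{m_j, \ldots, m_{j+1}-1}, so the segments of
#' one IMF partition the samples between its first and last minima; samples
#' outside that span belong to no segment. Scales shared by several IMFs are
#' pooled: the global scale set is the union over all IMFs.
#'
#' @param decomposition An [emd()] result.
#' @return An object of class `intrinsic_scales`: a list with `scales`
#'   (sorted unique intrinsic scales, samples), `counts` (number of segments
#'   per scale), `retained` (number of samples covered per scale), `per_imf`
#'   (list of per-IMF inter-minima distance vectors) and `labels` (an
#'   `n x k` integer matrix giving each sample's segment length per IMF, NA
#'   outside any segment). [generics::tidy()] returns one row per IMF and
#'   scale.
#' @examples
#' dec <- emd(cumulative_profile(generate_fgn(1024, 0.5, seed = 1)))
#' head(tidy(intrinsic_scales(dec)))
#' @export
intrinsic_scales <- function(decomposition) {
  stopifnot(inherits(decomposition, "emd_decomposition"))
  k <- ncol(decomposition$imfs)
  n <- decomposition$source_length
  labels <- matrix(NA_integer_, nrow = n, ncol = k)
  per_imf <- vector("list", k)
  for (j in seq_len(k)) {
    imf <- decomposition$imfs[, j]
    if (length(imf) < 3) next
    mins <- find_extrema(imf)$minima
    if (length(mins) < 2) { per_imf[[j]] <- integer(0); next }
    d <- diff(mins)
    per_imf[[j]] <- d
    labels[mins[1]:(mins[length(mins)] - 1L), j] <-
      rep.int(d, d)
  }
  all_d <- unlist(per_imf)
  if (is.null(all_d) || length(all_d) == 0) {
    abort("No intrinsic scales: no IMF has two local minima.",
          class = "emddfa_no_scales")
  }
  scales <- sort(unique(all_d))
  counts <- vapply(scales, function(s) sum(all_d == s), integer(1))
  retained <- vapply(scales, function(s) sum(labels == s, na.rm = TRUE), integer(1))
  names(per_imf) <- colnames(decomposition$imfs)
  structure(
    list(scales = as.integer(scales), counts = counts, retained = retained,
         per_imf = per_imf, labels = labels, source_length = n),
    class = "intrinsic_scales"
  )
}

#' @export
print.intrinsic_scales <- function(x, ...) {
  cat(sprintf("<intrinsic_scales> %d unique scales from %d IMFs (range %d-%d samples)\n",
              length(x$scales), length(x$per_imf),
              min(x$scales), max(x$scales)))
  invisible(x)
}

#' @rdname intrinsic_scales
#' @param x An `intrinsic_scales` object.
#' @param ... Unused.
#' @method tidy intrinsic_scales
#' @export
tidy.intrinsic_scales <- function(x, ...) {
  rows <- purrr::imap(x$per_imf, function(d, nm) {
    if (length(d) == 0) return(NULL)
    t <- table(d)
    tibble::tibble(imf = nm, scale = as.integer(names(t)),
                   n_segments = as.integer(t))
  })
  dplyr::bind_rows(rows)
}

#' Reconstruct the signal component at one intrinsic scale
#'
#' For a chosen intrinsic scale `s`, every IMF is masked so that only samples
#' lying in inter-minima segments of length exactly `s` are kept and zeros are
#' substituted everywhere else; the per-scale series \eqn{Y_s} is the
#' elementwise sum of the masked IMFs (the residual trend is excluded).
#'
#' @param decomposition An [emd()] result.
#' @param scales_table The matching [intrinsic_scales()] result.
#' @param s Intrinsic scale in samples; must be a member of
#'   `scales_table$scales`.
#' @return A list with `y` (numeric length-`n` series, zeros off-mask) and
#'   `mask` (logical, TRUE where at least one IMF contributed).
#' @export
reconstruct_at_scale <- function(decomposition, scales_table, s) {
  stopifnot(inherits(decomposition, "emd_decomposition"),
            inherits(scales_table, "intrinsic_scales"))
  check_scalar(s, "s", positive = TRUE)
  if (!(s %in% scales_table$scales)) {
    abort(sprintf("Scale %g is not an intrinsic scale of this decomposition.", s),
          class = "emddfa_invalid_scale")
  }
  reconstruct_at_scale_set(decomposition, scales_table, as.integer(s))
}

# Internal: reconstruction keeping all segments whose length is in `s_set`
# (used both for exact scale matching and for merged scale bins).
reconstruct_at_scale_set <- function(decomposition, scales_table, s_set) {
  n <- decomposition$source_length
  y <- numeric(n)
  mask <- logical(n)
  for (j in seq_len(ncol(decomposition$imfs))) {
    keep <- scales_table$labels[, j] %in% s_set
    if (any(keep)) {
      y[keep] <- y[keep] + decomposition$imfs[keep, j]
      mask <- mask | keep
    }
  }
  list(y = y, mask = mask)
}

#' Root-mean-square fluctuation of a per-scale series
#'
#' Computes \eqn{F(s)} for a per-scale reconstruction. Under the default
#' `"full"` normalization the sum of squares is divided by the full series
#' length `N` (zeros included), reading the RMS literally over the whole
#' series; under `"retained"` it is divided by the number of retained
#' (non-substituted) samples, making `F` the RMS amplitude of the surviving
#' oscillations. Because zero substitution leaves different sample counts at
#' different scales, the two normalizations scale differently; both are
#' exposed and the choice is recorded in results.
#'
#' @param y Per-scale series (zeros where masked out), as produced by
#'   [reconstruct_at_scale()].
#' @param mask Logical retained-sample mask of the same length.
#' @param normalization `"full"` or `"retained"`.
#' @return Non-negative scalar `F(s)`.
#' @examples
#' fluctuation_function(c(3, 0, 0, 0), c(TRUE, TRUE, TRUE, TRUE))    # 1.5
#' fluctuation_function(c(3, 0, 0, 0), c(TRUE, FALSE, FALSE, FALSE),
#'                      normalization = "retained")                  # 3
#' @export
fluctuation_function <- function(y, mask, normalization = c("full", "retained")) {
  normalization <- match.arg(normalization)
  check_numeric(y, "y")
  if (length(mask) != length(y)) {
    abort("`mask` must have the same length as `y`.",
          class = "emddfa_invalid_input")
  }
  n_ret <- sum(mask)
  if (n_ret == 0) {
    abort("No retained samples at this scale; F(s) is undefined.",
          class = "emddfa_empty_scale")
  }
  denom <- if (normalization == "full") length(y) else n_ret
  sqrt(sum(y[mask]^2) / denom)
}

#' Two-regime power-law fit of a fluctuation curve
#'
#' Fits the crossover model the method reports: in \eqn{(\log_{10} s,
#' \log_{10} F)} space, every admissible breakpoint between sorted scales is
#' scanned; two independent ordinary least-squares lines are fit to the left
#' and right parts and the breakpoint minimizing the total sum of squared
#' errors is selected (ties broken toward the smaller breakpoint). The left
#' slope is the short-term scaling exponent `alpha_short`, the right slope
#' `alpha_long`, and the crossover scale is the geometric mean of the two
#' scales adjacent to the selected breakpoint.
#'
#' With fewer than `2 * min_points_per_segment` usable scales the fit falls
#' back to a single global slope (`alpha_short == alpha_long`, crossover
#' undefined) and is flagged. When the two slopes differ by less than 0.05
#' the result is additionally flagged as having no distinct regimes.
#'
#' @param curve A data frame with columns `scale` and `fluctuation` (a
#'   [dfa()] or [emd_dfa()] curve works directly). Rows with non-finite or
#'   non-positive entries are dropped.
#' @param min_points_per_segment Minimum scales per segment (default 3; a
#'   two-point slope is always exact and meaningless).
#' @return An object of class `crossover_fit` with elements `alpha_short`,
#'   `alpha_long`, `crossover_scale` (samples; NA in fallback), `sse_total`,
#'   `r2_short`, `r2_long`, `n_points_short`, `n_points_long`,
#'   `single_regime_fallback`, `distinct_regimes`, plus the per-segment
#'   intercepts. [generics::glance()] returns a one-row tibble;
#'   [generics::tidy()] one row per segment.
#' @export
fit_crossover <- function(curve, min_points_per_segment = 3L) {
  stopifnot(is.data.frame(curve),
            all(c("scale", "fluctuation") %in% names(curve)))
  if (min_points_per_segment < 2) {
    abort("`min_points_per_segment` must be >= 2.",
          class = "emddfa_invalid_input")
  }
  ok <- is.finite(curve$scale) & is.finite(curve$fluctuation) &
    curve$scale > 0 & curve$fluctuation > 0
  df <- curve[ok, c("scale", "fluctuation")]
  df <- df[order(df$scale), ]
  ls <- log10(df$scale)
  lf <- log10(df$fluctuation)
  n <- length(ls)
  m <- as.integer(min_points_per_segment)

  single <- function() {
    if (n < 2) {
      abort("Need at least 2 usable scales to fit a slope.",
            class = "emddfa_invalid_input")
    }
    fit <- ols_line(ls, lf)
    structure(
      list(alpha_short = unname(fit["slope"]), alpha_long = unname(fit["slope"]),
           crossover_scale = NA_real_, breakpoint = NA_integer_,
           sse_total = unname(fit["sse"]),
           r2_short = unname(fit["r2"]), r2_long = unname(fit["r2"]),
           intercept_short = unname(fit["intercept"]),
           intercept_long = unname(fit["intercept"]),
           n_points_short = n, n_points_long = n,
           single_regime_fallback = TRUE, distinct_regimes = FALSE,
           curve = tibble::as_tibble(df)),
      class = "crossover_fit")
  }
  if (n < 2L * m) return(single())

  best <- NULL
  best_sse <- Inf
  # improvements below rounding noise count as ties, which resolve to the
  # smaller breakpoint index
  tie_tol <- 1e-10 * sum((lf - mean(lf))^2)
  for (b in seq(m, n - m)) {
    left <- ols_line(ls[1:b], lf[1:b])
    right <- ols_line(ls[(b + 1):n], lf[(b + 1):n])
    sse <- left[["sse"]] + right[["sse"]]
    if (is.null(best) || sse < best_sse - tie_tol) {
      best_sse <- sse
      best <- list(b = b, left = left, right = right)
    }
  }
  alpha_s <- best$left[["slope"]]
  alpha_l <- best$right[["slope"]]
  structure(
    list(alpha_short = alpha_s, alpha_long = alpha_l,
         crossover_scale = sqrt(df$scale[best$b] * df$scale[best$b + 1]),
         breakpoint = best$b,
         sse_total = best_sse,
         r2_short = best$left[["r2"]], r2_long = best$right[["r2"]],
         intercept_short = best$left[["intercept"]],
         intercept_long = best$right[["intercept"]],
         n_points_short = best$b, n_points_long = n - best$b,
         single_regime_fallback = FALSE,
         distinct_regimes = abs(alpha_s - alpha_l) >= 0.05,
         curve = tibble::as_tibble(df)),
    class = "crossover_fit")
}

#' @export
print.crossover_fit <- function(x, ...) {
  if (x$single_regime_fallback) {
    cat(sprintf("<crossover_fit> single regime: alpha = %.3f (%d scales)\n",
                x$alpha_short, x$n_points_short))
  } else {
    cat(sprintf(
      "<crossover_fit> alpha_short = %.3f, alpha_long = %.3f, crossover = %.2f samples%s\n",
      x$alpha_short, x$alpha_long, x$crossover_scale,
      if (!x$distinct_regimes) " (regimes not distinct)" else ""))
  }
  invisible(x)
}

#' @rdname fit_crossover
#' @param x A `crossover_fit` object.
#' @param ... Unused.
#' @method glance crossover_fit
#' @export
glance.crossover_fit <- function(x, ...) {
  tibble::tibble(
    alpha_short = x$alpha_short, alpha_long = x$alpha_long,
    crossover_scale = x$crossover_scale,
    sse_total = x$sse_total, r2_short = x$r2_short, r2_long = x$r2_long,
    n_points_short = x$n_points_short, n_points_long = x$n_points_long,
    single_regime_fallback = x$single_regime_fallback,
    distinct_regimes = x$distinct_regimes
  )
}

#' @rdname fit_crossover
#' @method tidy crossover_fit
#' @export
tidy.crossover_fit <- function(x, ...) {
  tibble::tibble(
    segment = c("short", "long"),
    alpha = c(x$alpha_short, x$alpha_long),
    intercept = c(x$intercept_short, x$intercept_long),
    r2 = c(x$r2_short, x$r2_long),
    n_scales = c(x$n_points_short, x$n_points_long)
  )
}

#' EMD-embedded detrended fluctuation analysis
#'
#' Runs the full pipeline on a magnitude series (or any univariate series):
#' the mean-removed cumulative profile is decomposed by [emd()]; the residual
#' trend is discarded; intrinsic scales are read off as inter-minima distances
#' within each IMF ([intrinsic_scales()]); for every intrinsic scale the
#' signal is reconstructed with zeros substituted outside segments of that
#' length ([reconstruct_at_scale()]) and its RMS fluctuation computed
#' ([fluctuation_function()]); finally the fluctuation curve is fit with a
#' two-regime power law ([fit_crossover()]) yielding the short- and long-term
#' scaling exponents and the crossover scale.
#'
#' Because the time scales are intrinsic to (derived from) the signal rather
#' than a fixed dyadic grid, and the trend removed is the decomposition's own
#' residual, the method resolves scale-dependent fractal structure -- notably
#' a short/long crossover -- that conventional DFA blurs.
#'
#' By default the analysis is restricted to intrinsic scales in
#' `[min_scale, N / 8]` (mirroring the window bounds of conventional DFA:
#' scales of 2-3 samples are at the quantization limit, and the few
#' segments longer than N/8 belong to the slowest, trend-contaminated
#' modes), and neighbouring scales are pooled into bins holding at least
#' `min_segments` inter-minima segments each (`bin_scales = TRUE`). A scale
#' whose RMS is estimated from a single segment carries only a couple of
#' degrees of freedom; pooling keeps every curve point comparably reliable
#' while leaving the dense small scales at full resolution. Each bin reports
#' its retained-weighted geometric mean scale. Set `bin_scales = FALSE` for
#' exact integer-scale matching. The two-regime fit additionally requires
#' each regime to hold at least `min_segment_fraction` of the curve points,
#' so a regime slope is never read off a handful of extreme scales.
#'
#' Scales whose reconstruction retains no samples are dropped with a warning.
#' If fewer than 6 usable scales remain, a single-slope fallback is reported
#' and flagged.
#'
#' @param series A [magnitude_series()] tibble or numeric vector, length
#'   >= 512.
#' @param sample_rate Sampling rate in Hz; taken from `series` if it carries
#'   one, else defaults to 1 (scales then reported in samples only).
#' @param normalization Normalization of `F(s)`; see
#'   [fluctuation_function()]. Default `"retained"`: the alternative
#'   `"full"` folds the scale-dependent retained-sample count into `F(s)`,
#'   which distorts local slopes by up to +-0.5.
#' @param max_imfs,sd_threshold,max_sift Passed to [emd()].
#' @param min_scale Smallest intrinsic scale analyzed, in samples
#'   (default 4).
#' @param max_scale Largest intrinsic scale analyzed; default `NULL` means
#'   `length(series) / 8`.
#' @param bin_scales Pool neighbouring scales into equal-reliability bins
#'   (default TRUE). `FALSE` gives exact integer-scale matching.
#' @param min_segments Minimum inter-minima segments per curve point when
#'   `bin_scales = TRUE` (default 10).
#' @param min_points_per_segment Hard minimum scales per fitted regime,
#'   passed to [fit_crossover()] (default 3).
#' @param min_segment_fraction Minimum fraction of curve points per fitted
#'   regime (default 0.25); the effective minimum is the larger of this and
#'   `min_points_per_segment`.
#' @param keep_decomposition Keep the full EMD in the result (default FALSE
#'   to keep result objects light).
#' @return An object of class `emd_dfa`: a list with `curve` (a tibble with
#'   columns `scale` (samples), `scale_ms`, `fluctuation`, `n_retained`,
#'   `n_segments`), `fit` (a [fit_crossover()] result), `alpha_global` (the
#'   single-slope fit over all analyzed scales), `n_imfs` and `config`.
#'   [generics::glance()] returns the scaling exponents and crossover (in
#'   samples and ms) as a one-row tibble; [generics::tidy()] returns the
#'   curve; `autoplot()` draws the log-log curve with the fitted segments.
#' @examples
#' \donttest{
#' x <- generate_fgn(2048, hurst = 0.7, seed = 1)
#' res <- emd_dfa(x, sample_rate = 1000)
#' glance(res)
#' }
#' @export
emd_dfa <- function(series, sample_rate = NULL,
                    normalization = c("retained", "full"),
                    max_imfs = 12L, sd_threshold = 0.2, max_sift = 200L,
                    min_scale = 4L, max_scale = NULL,
                    bin_scales = TRUE, min_segments = 10L,
                    min_points_per_segment = 3L,
                    min_segment_fraction = 0.25,
                    keep_decomposition = FALSE) {
  normalization <- match.arg(normalization)
  if (is.null(sample_rate)) {
    sample_rate <- attr(series, "sample_rate") %||% 1
  }
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  d <- as_series(series, "series")
  if (length(d) < 512) {
    abort(sprintf(
      "Series has %d samples; at least 512 are required for a stable decomposition.",
      length(d)), class = "emddfa_invalid_input")
  }
  if (is.null(max_scale)) max_scale <- length(d) / 8
  check_scalar(min_scale, "min_scale", positive = TRUE)
  check_scalar(max_scale, "max_scale", positive = TRUE)

  profile <- cumulative_profile(d)
  dec <- emd(profile, max_imfs = max_imfs, sd_threshold = sd_threshold,
             max_sift = max_sift)
  tab <- intrinsic_scales(dec)

  in_band <- tab$scales >= min_scale & tab$scales <= max_scale
  if (!any(in_band)) {
    abort("No intrinsic scales inside the analyzed band.",
          class = "emddfa_no_scales")
  }
  bins <- if (bin_scales) {
    bin_scale_set(tab$scales[in_band], tab$counts[in_band],
                  tab$retained[in_band], min_segments)
  } else {
    purrr::map(which(in_band), function(i)
      list(scales = tab$scales[i], rep = as.numeric(tab$scales[i])))
  }

  rows <- purrr::map(bins, function(b) {
    rec <- reconstruct_at_scale_set(dec, tab, b$scales)
    n_ret <- sum(rec$mask)
    if (n_ret == 0) return(NULL)
    f <- fluctuation_function(rec$y, rec$mask, normalization)
    tibble::tibble(
      scale = b$rep,
      fluctuation = f,
      n_retained = n_ret,
      n_segments = sum(tab$counts[tab$scales %in% b$scales])
    )
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("%d scale(s) retained no samples and were dropped.", dropped),
         class = "emddfa_dropped_scales")
  }
  curve <- dplyr::bind_rows(rows)
  curve$scale_ms <- curve$scale / sample_rate * 1000
  curve <- curve[, c("scale", "scale_ms", "fluctuation", "n_retained",
                     "n_segments")]

  min_pts <- max(as.integer(min_points_per_segment),
                 ceiling(min_segment_fraction * nrow(curve)))
  fit <- if (nrow(curve) < 6) {
    fit_crossover(curve,
                  min_points_per_segment = max(2L, floor(nrow(curve) / 2)))
  } else {
    fit_crossover(curve, min_points_per_segment = min_pts)
  }
  if (nrow(curve) < 6 && !fit$single_regime_fallback) {
    fit$single_regime_fallback <- TRUE
    fit$crossover_scale <- NA_real_
  }
  gfit <- ols_line(log10(curve$scale), log10(curve$fluctuation))

  structure(
    list(curve = curve, fit = fit,
         alpha_global = unname(gfit["slope"]),
         n_imfs = ncol(dec$imfs),
         decomposition = if (keep_decomposition) dec else NULL,
         config = list(sample_rate = sample_rate, normalization = normalization,
                       max_imfs = as.integer(max_imfs),
                       sd_threshold = sd_threshold,
                       max_sift = as.integer(max_sift),
                       min_scale = as.integer(min_scale),
                       max_scale = max_scale,
                       bin_scales = bin_scales,
                       min_segments = as.integer(min_segments),
                       min_points_per_segment = as.integer(min_points_per_segment),
                       min_segment_fraction = min_segment_fraction)),
    class = "emd_dfa")
}

# Internal: pool consecutive sorted scales until each bin holds at least
# `min_segments` inter-minima segments; an undersized remainder joins the
# last bin. Representative scale is the retained-weighted geometric mean.
bin_scale_set <- function(scales, counts, retained, min_segments) {
  bins <- list()
  cur <- integer(0)
  cur_cnt <- 0L
  for (i in seq_along(scales)) {
    cur <- c(cur, scales[i])
    cur_cnt <- cur_cnt + counts[i]
    if (cur_cnt >= min_segments) {
      bins[[length(bins) + 1L]] <- cur
      cur <- integer(0); cur_cnt <- 0L
    }
  }
  if (length(cur)) {
    if (length(bins)) {
      bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    } else {
      bins[[1]] <- cur
    }
  }
  purrr::map(bins, function(s) {
    w <- retained[match(s, scales)]
    list(scales = s, rep = exp(sum(w * log(s)) / sum(w)))
  })
}

#' @export
print.emd_dfa <- function(x, ...) {
  cat(sprintf("<emd_dfa> %d intrinsic scales from %d IMFs (%s normalization)\n",
              nrow(x$curve), x$n_imfs, x$config$normalization))
  print(x$fit)
  invisible(x)
}

#' @rdname emd_dfa
#' @param x An `emd_dfa` object.
#' @param ... Unused.
#' @method tidy emd_dfa
#' @export
tidy.emd_dfa <- function(x, ...) x$curve

#' @rdname emd_dfa
#' @method glance emd_dfa
#' @export
glance.emd_dfa <- function(x, ...) {
  g <- glance.crossover_fit(x$fit)
  fs <- x$config$sample_rate
  tibble::tibble(
    alpha_short = g$alpha_short, alpha_long = g$alpha_long,
    alpha_global = x$alpha_global,
    crossover_scale = g$crossover_scale,
    crossover_ms = g$crossover_scale / fs * 1000,
    r2_short = g$r2_short, r2_long = g$r2_long,
    n_scales = nrow(x$curve), n_imfs = x$n_imfs,
    single_regime_fallback = g$single_regime_fallback,
    distinct_regimes = g$distinct_regimes,
    normalization = x$config$normalization
  )
}

#' Plot an EMD-DFA or DFA fluctuation curve
#'
#' Log-log plot of the fluctuation function with the fitted power-law
#' segment(s) overlaid.
#'
#' @param object An `emd_dfa` or `dfa` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot emd_dfa
#' @export
autoplot.emd_dfa <- function(object, ...) {
  plot_fluctuation(object$curve, object$fit,
                   xlab = "intrinsic scale s (samples)")
}

# Internal: shared curve + fit plot
plot_fluctuation <- function(curve, fit, xlab) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$scale, y = .data$fluctuation)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = "F(s)")
  if (is.null(fit)) return(p)
  seg <- segment_lines(fit)
  p + ggplot2::geom_line(data = seg,
                         ggplot2::aes(x = .data$scale, y = .data$fluctuation,
                                      group = .data$segment),
                         colour = "red3", linewidth = 0.4)
}

# Internal: fitted line coordinates for plotting
segment_lines <- function(fit) {
  cv <- fit$curve
  if (fit$single_regime_fallback || is.na(fit$crossover_scale)) {
    s <- range(cv$scale)
    return(tibble::tibble(
      segment = "global",
      scale = s,
      fluctuation = 10^(fit$intercept_short + fit$alpha_short * log10(s))))
  }
  b <- fit$breakpoint
  s1 <- range(cv$scale[1:b]); s2 <- range(cv$scale[(b + 1):nrow(cv)])
  tibble::tibble(
    segment = rep(c("short", "long"), each = 2),
    scale = c(s1, s2),
    fluctuation = c(10^(fit$intercept_short + fit$alpha_short * log10(s1)),
                    10^(fit$intercept_long + fit$alpha_long * log10(s2))))
}
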