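#' Full sway analysis of one COP trajectory
#'
#' Bundles the complete per-trial workflow: the magnitude series is formed
#' from the 2-D trajectory, EMD-DFA yields the short- and long-term scaling
#' exponents and the crossover scale, and the classical summary metrics
#' (sway speed, 95% confidence-ellipse area) are computed from the raw
#' trajectory. Optionally, conventional DFA of the same magnitude series is
#' attached for comparison.
#'
#' @param traj A [cop_trajectory()].
#' @param with_dfa Also run conventional [dfa()] on the magnitude series
#'   (default FALSE).
#' @param label Optional trial label carried into summaries.
#' @param ... Passed on to [emd_dfa()].
#' @return An object of class `sway_analysis`: a list with `summary` (a
#'   one-row tibble: `speed` mm/s, `area` mm^2, `alpha_short`, `alpha_long`,
#'   `alpha_global`, `crossover_scale` samples, `crossover_ms`,
#'   `single_regime_fallback`, `distinct_regimes`, and `dfa_alpha` when
#'   requested), `curve`, `fit`, `dfa` (or NULL), `config` and `meta`.
#'   [generics::glance()] returns the summary row.
#' @examples
#' \donttest{
#' traj <- generate_cop2d(n = 2048, sample_rate = 100, seed = 2)
#' glance(analyze_sway(traj))
#' }
#' @export
analyze_sway <- function(traj, with_dfa = FALSE, label = NULL, ...) {
  stopifnot(inherits(traj, "cop_trajectory"))
  mag <- magnitude_series(traj)
  res <- emd_dfa(mag, ...)
  metrics <- sway_metrics(traj)
  g <- glance(res)
  dfa_res <- if (with_dfa) dfa(mag$magnitude)
  summary <- tibble::tibble(
    speed = metrics$speed,
    area = metrics$area,
    alpha_short = g$alpha_short,
    alpha_long = g$alpha_long,
    alpha_global = g$alpha_global,
    crossover_scale = g$crossover_scale,
    crossover_ms = g$crossover_ms,
    single_regime_fallback = g$single_regime_fallback,
    distinct_regimes = g$distinct_regimes
  )
  if (with_dfa) summary$dfa_alpha <- dfa_res$alpha
  meta <- attr(traj, "meta") %||% list()
  if (!is.null(label)) meta$label <- label
  structure(
    list(summary = summary, curve = res$curve, fit = res$fit,
         emd_dfa = res, dfa = dfa_res,
         config = res$config, meta = meta),
    class = "sway_analysis")
}

#' @export
print.sway_analysis <- function(x, ...) {
  cat("<sway_analysis>\n")
  cat(sprintf("  speed %.3f mm/s, area %.3f mm^2\n",
              x$summary$speed, x$summary$area))
  print(x$fit)
  invisible(x)
}

#' @rdname analyze_sway
#' @param x A `sway_analysis` object.
#' @param ... Unused (for `glance`).
#' @method glance sway_analysis
#' @export
glance.sway_analysis <- function(x, ...) x$summary

#' Average sway summaries across trials
#'
#' Arithmetic mean of every numeric summary column over a batch of analyzed
#' trials (the standard way repeated trials per condition are reported),
#' with the per-trial rows retained.
#'
#' @param results List of `sway_analysis` objects.
#' @return A tibble with one row per trial plus a final `"mean"` row.
#' @export
summarize_trials <- function(results) {
  rows <- summary_rows(results)
  num <- dplyr::summarise(rows, dplyr::across(dplyr::where(is.numeric), mean))
  dplyr::bind_rows(rows, dplyr::bind_cols(tibble::tibble(trial = "mean"), num))
}
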