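#' Column mapping for delimited force-plate exports
#'
#' Describes how to pull a COP trajectory out of a delimited text export
#' (Bioware-style or any CSV/TSV): which columns hold the mediolateral and
#' anteroposterior displacements, an optional time column, the delimiter,
#' decimal separator, header rows to skip, and a multiplicative factor that
#' converts the file's length unit to millimetres.
#'
#' @param x,y Column name or 1-based index of the mediolateral (x) and
#'   anteroposterior (y) displacement columns; must differ.
#' @param time Optional column name/index of a time stamp column (seconds),
#'   used to cross-check the stated sampling rate.
#' @param delim Field delimiter (default ",").
#' @param decimal_mark Decimal separator (default ".").
#' @param skip Extra header lines to skip before the column header row.
#' @param scale_to_mm Factor multiplying x/y to yield mm (default 1; use
#'   1000 for exports in metres, 10 for centimetres).
#' @return An object of class `column_map`.
#' @examples
#' column_map(x = "COPx", y = "COPy", time = "t", scale_to_mm = 1000)
#' @export
column_map <- function(x = "x", y = "y", time = NULL, delim = ",",
                       decimal_mark = ".", skip = 0L, scale_to_mm = 1) {
  if (identical(x, y)) {
    abort("`x` and `y` must map to distinct columns.",
          class = "emddfa_invalid_input")
  }
  check_scalar(scale_to_mm, "scale_to_mm", positive = TRUE)
  structure(list(x = x, y = y, time = time, delim = delim,
                 decimal_mark = decimal_mark, skip = as.integer(skip),
                 scale_to_mm = scale_to_mm),
            class = "column_map")
}

# Internal: resolve a name-or-index column reference against a data frame
resolve_column <- function(df, ref, what, path) {
  if (is.numeric(ref)) {
    if (ref < 1 || ref > ncol(df)) {
      abort(sprintf("File '%s' has no column %d for %s.", path, ref, what),
            class = "emddfa_io_error")
    }
    return(as.integer(ref))
  }
  i <- match(ref, names(df))
  if (is.na(i)) {
    abort(sprintf("File '%s' has no column named '%s' for %s.",
                  path, ref, what),
          class = "emddfa_io_error")
  }
  i
}

#' Read a COP trajectory from a delimited text file
#'
#' Reads a Bioware-style delimited export according to a [column_map()],
#' validates it, and returns a [cop_trajectory()]. Rows with non-finite x or
#' y are dropped with a warning stating the count. If the map names a time
#' column, the median sampling interval is checked against `sample_rate` and
#' a mismatch beyond 1% is an error; without a time column the stated rate is
#' trusted.
#'
#' @param path Path to the file.
#' @param sample_rate Sampling rate in Hz.
#' @param map A [column_map()]; defaults to columns `x` and `y`, comma
#'   delimiter, mm units.
#' @param meta Optional named list of trial annotations.
#' @return A [cop_trajectory()].
#' @export
read_cop_trajectory <- function(path, sample_rate, map = column_map(),
                                meta = list()) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "emddfa_io_error")
  }
  stopifnot(inherits(map, "column_map"))
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  df <- tryCatch(
    readr::read_delim(
      path, delim = map$delim, skip = map$skip,
      locale = readr::locale(decimal_mark = map$decimal_mark),
      show_col_types = FALSE, progress = FALSE,
      col_types = readr::cols(.default = readr::col_double())),
    error = function(e) {
      abort(sprintf("Failed to parse '%s': %s", path, conditionMessage(e)),
            class = "emddfa_io_error")
    })
  xi <- resolve_column(df, map$x, "x (mediolateral)", path)
  yi <- resolve_column(df, map$y, "y (anteroposterior)", path)
  x <- df[[xi]]
  y <- df[[yi]]
  t <- if (!is.null(map$time)) df[[resolve_column(df, map$time, "time", path)]]

  ok <- is.finite(x) & is.finite(y)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warn(sprintf("Dropped %d row(s) with non-finite x/y from '%s'.",
                 n_bad, path),
         class = "emddfa_dropped_rows")
    x <- x[ok]; y <- y[ok]
    if (!is.null(t)) t <- t[ok]
  }
  if (length(x) < 2) {
    abort(sprintf("File '%s' has fewer than 2 valid samples.", path),
          class = "emddfa_io_error")
  }
  if (!is.null(t) && length(t) >= 2) {
    dt <- stats::median(diff(t))
    if (!is.finite(dt) || dt <= 0 ||
        abs(dt - 1 / sample_rate) > 0.01 / sample_rate) {
      abort(sprintf(
        "File '%s': median sampling interval %.6g s disagrees with sample_rate %g Hz by more than 1%%.",
        path, dt, sample_rate), class = "emddfa_io_error")
    }
  }
  cop_trajectory(
    tibble::tibble(x = x * map$scale_to_mm, y = y * map$scale_to_mm),
    sample_rate = sample_rate,
    meta = c(meta, list(source = path, n_dropped_rows = n_bad)))
}

#' Write a simulated trajectory as a delimited file
#'
#' Writes the `t,x,y` CSV format that [read_cop_trajectory()] accepts with
#' the default [column_map()].
#'
#' @param traj A [cop_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cop_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cop_trajectory"))
  df <- tibble::tibble(
    t = (seq_len(nrow(traj)) - 1) / sample_rate(traj),
    x = traj$x, y = traj$y)
  readr::write_csv(df, path)
  invisible(path)
}

# Internal: flatten an analysis bundle to an ordered, JSON-ready list.
# Key order is fixed so serialization is canonical.
bundle_to_list <- function(x) {
  stopifnot(inherits(x, "sway_analysis"))
  list(
    software = "emddfa",
    version = as.character(utils::packageVersion("emddfa")),
    meta = x$meta,
    config = x$config,
    summary = as.list(x$summary),
    curve = list(
      scale = x$curve$scale,
      scale_ms = x$curve$scale_ms,
      fluctuation = x$curve$fluctuation,
      n_retained = x$curve$n_retained,
      n_segments = x$curve$n_segments
    ),
    dfa = if (!is.null(x$dfa)) list(
      alpha = x$dfa$alpha,
      scale = x$dfa$curve$scale,
      fluctuation = x$dfa$curve$fluctuation
    )
  )
}

#' Write an analysis result bundle
#'
#' Serializes one [analyze_sway()] result (or a list of them) either as a
#' JSON bundle -- scaling exponents, crossover in samples and ms, speed,
#' area, the full fluctuation curve, the effective configuration, seeds when
#' known, and the software version -- or as a flat CSV of summary rows for
#' batch concatenation. JSON numbers carry 17 significant digits, so a
#' write/read/write round trip is byte-identical.
#'
#' @param x A `sway_analysis` object or list of them.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "sway_analysis")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "sway_analysis")))
  if (format == "json") {
    payload <- if (length(x) == 1L) bundle_to_list(x[[1]]) else
      lapply(x, bundle_to_list)
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                             pretty = TRUE, null = "null", na = "null")
    writeLines(json, path, useBytes = TRUE)
  } else {
    readr::write_csv(summary_rows(x), path)
  }
  invisible(path)
}

# Internal: per-trial summary rows for CSV output
summary_rows <- function(results) {
  dplyr::bind_rows(lapply(results, function(r) {
    dplyr::bind_cols(
      tibble::tibble(trial = r$meta$label %||% r$meta$source %||% NA_character_),
      r$summary)
  }))
}

#' Read back a JSON result bundle
#'
#' Restores the list structure written by [write_result()] (tibbles for the
#' curves). Numeric fields are restored bit-exactly.
#'
#' @param path Path to a JSON bundle.
#' @return A list (one bundle) or list of lists (batch).
#' @export
read_result <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "emddfa_io_error")
  }
  jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
}
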