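#' @importFrom rlang abort warn %||%
#' @importFrom stats cov fft qchisq rnorm spec.pgram
NULL

# Internal: validate a numeric vector argument
check_numeric <- function(x, name, min_len = 1L, finite = TRUE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric, not %s.", name, class(x)[1]),
          class = "emddfa_invalid_input")
  }
  if (length(x) < min_len) {
    abort(sprintf("`%s` must have at least %d samples, got %d.",
                  name, min_len, length(x)),
          class = "emddfa_invalid_input")
  }
  if (finite && !all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name),
          class = "emddfa_invalid_input")
  }
  invisible(x)
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "emddfa_invalid_input")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name),
          class = "emddfa_invalid_input")
  }
  invisible(x)
}

# Internal: run `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators funnel through this so they are pure in (args, seed).
with_seed <- function(seed, expr) {
  check_scalar(seed, "seed")
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion")
}

# Internal: ordinary least squares y ~ x returning c(intercept, slope, sse, r2)
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  syy <- sum((y - my)^2)
  r2 <- if (syy > 0) 1 - sse / syy else 1
  c(intercept = intercept, slope = slope, sse = sse, r2 = r2)
}
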