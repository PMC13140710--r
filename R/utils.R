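# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_agg <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "aggkinetics_error")))
}

# validation error: bad input values (non-monotonic time, negative counts, ...)
stop_validation <- function(fmt, ...) {
  stop_agg(fmt, ..., class = "aggkinetics_validation_error")
}

# format error: file could not be parsed into the expected schema
stop_format <- function(fmt, ...) {
  stop_agg(fmt, ..., class = "aggkinetics_format_error")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stop_validation("'%s' = %g is outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

assert_strictly_increasing <- function(x, name) {
  if (any(!is.finite(x)))
    stop_validation("'%s' contains non-finite values", name)
  if (any(diff(x) <= 0))
    stop_validation("'%s' must be strictly increasing (first violation at index %d)",
                    name, which(diff(x) <= 0)[1] + 1L)
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  assert_scalar_number(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

# Linear interpolation of interior NA runs of length <= max_run; longer runs
# (or NA at the ends) are a validation failure because extrapolated values
# would bias lag estimates.
fill_short_gaps <- function(x, time, max_run = 2L, what = "series") {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (r$lengths[i] > max_run)
      stop_validation("%s has a gap of %d consecutive missing values (max %d allowed)",
                      what, r$lengths[i], max_run)
    if (starts[i] == 1L || ends[i] == length(x))
      stop_validation("%s has missing values at its boundary", what)
  }
  approx(time[!is.na(x)], x[!is.na(x)], xout = time)$y
}

# r-squared of a fitted nls-type model against observed y
r_squared <- function(observed, fitted) {
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((observed - fitted)^2) / ss_tot
}
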