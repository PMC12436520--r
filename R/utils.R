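# Internal helpers shared across modules.

# Validate that `x` is a single finite number satisfying `ok`.
check_scalar <- function(x, name, ok = function(v) TRUE, msg = "is invalid") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !ok(x)) {
    abort(sprintf("`%s` %s (got %s)", name, msg, format(x)[1]))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_scalar(x, name, function(v) v > 0, "must be a positive finite number")
}

check_nonneg <- function(x, name) {
  check_scalar(x, name, function(v) v >= 0, "must be a non-negative finite number")
}

# Require columns in a data frame; error names the first missing column.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column `%s`", what, missing[1]))
  }
  invisible(df)
}

# Reflect coordinates into [0, L] (reflective boundary, applied repeatedly
# in case a step overshoots by more than one field length).
reflect_into <- function(x, L) {
  # map onto a sawtooth of period 2L
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}
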