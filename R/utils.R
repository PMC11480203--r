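# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed.  Generators consume one user-facing
# seed; independent sub-streams (per stage, per factor, per cohort) are
# derived by fixed offsets so that adding a stage never reshuffles the
# randomness of another.  Kept below 2^31 - 1 for portability.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "cooccupy_invalid_config")
  }
  ok <- if (strict_lower) x > lower else x >= lower
  if (!ok || x > upper) {
    abort(sprintf("`%s` = %s is out of range [%s, %s].", name, format(x),
                  if (strict_lower) paste0(">", lower) else lower, upper),
          class = "cooccupy_invalid_config")
  }
  invisible(x)
}

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "cooccupy_bad_input")
  }
  invisible(data)
}

# Numeric sample columns of a wide table (everything except the id columns).
sample_columns <- function(data, id_cols) {
  setdiff(names(data), id_cols)
}
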