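# Internal helpers shared across modules.

# Minimum-jerk unit step: s(0)=0, s(1)=1, zero velocity/acceleration at ends.
min_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  tau^3 * (10 - 15 * tau + 6 * tau^2)
}

# Smooth bump rising 0 -> 1 on [0, peak] and falling back to `rest` on
# [peak, 1]; built from two minimum-jerk segments so it is C^2 everywhere.
min_jerk_bump <- function(tau, peak = 0.5, rest = 0) {
  up <- min_jerk(tau / peak)
  down <- 1 - (1 - rest) * min_jerk((tau - peak) / (1 - peak))
  ifelse(tau <= peak, up, down)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s must have columns: %s (missing: %s)",
                  what, paste(cols, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Derive a reproducible child seed from a base seed and a stream label.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1021L + sum(utf8ToInt(stream)) * 7L) %% 2147483562L
}
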