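# Internal helpers shared across the package.

# Classed error so callers and tests can discriminate failure modes.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "emocascade_error")))
}

#' Round half away from zero
#'
#' Display rounding used throughout the package: half-values round away from
#' zero (so 13.05 -> 13.1), unlike [base::round()]'s round-half-to-even. All
#' internal arithmetic is carried at full precision; this is applied only when
#' a value is printed or written.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1, the display precision
#'   for percentages).
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small slack absorbs binary representation error in values like 13.049999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Format a percentage (or NA) for display / CSV output at 1 decimal.
fmt1 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", round_half_up(x, 1)))
}

# percentage from exact counts
pct <- function(k, n) 100 * k / n

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
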