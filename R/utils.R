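#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; all percentages and ratios
#' reported by this package use the conventional half-up rule instead, so
#' printed summary values are reproducible digit-for-digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(2.25, 1) # 2.3, where round(2.25, 1) gives 2.2
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by a relative epsilon so values that are exactly .5 after decimal
  # arithmetic (e.g. 38.15 stored as 38.149999...) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Derive a reproducible stage seed from a master seed
#'
#' Pipelines run several stochastic stages off one user-supplied seed. Each
#' stage gets its own substream seed derived from the master seed and the
#' stage name, so stages can be re-run individually without replaying the
#' whole pipeline. Kept below 2^31 to stay a valid R integer.
#'
#' @param seed master integer seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# internal: percentage with half-up rounding, NA-safe on zero denominators
pct_of <- function(num, den, digits = 1) {
  if (is.na(den) || den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

# internal: stop unless condition, with sprintf-style message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
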