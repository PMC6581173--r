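#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used for
#' all reported budget figures (so 0.215 reports as 0.22, not the IEEE
#' round-half-even 0.21).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.215, 2)
#' round_half_up(2.5, 0)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# shared argument checks -----------------------------------------------------

check_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || (!allow_zero && x == min)) {
    abort(sprintf(
      "`%s` must be %s %s.", name,
      if (allow_zero) ">=" else ">", format(min)
    ))
  }
  invisible(x)
}

check_positive <- function(x, name) check_number(x, name, min = 0, allow_zero = FALSE)
check_nonneg <- function(x, name) check_number(x, name, min = 0, allow_zero = TRUE)

# derive a reproducible sub-seed for a named simulation stream from the one
# config seed, keeping the result inside the 32-bit integer range
stream_seed <- function(seed, stream) {
  offsets <- c(
    growth = 11L, tracer = 23L, fractionation = 37L,
    assay = 53L, survey = 71L
  )
  off <- offsets[[stream]]
  (as.integer(seed) %% 2000000000L) + off
}
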