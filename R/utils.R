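#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages in this
#' package follow the conventional half-up rule (80.25 -> 80.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## internal: stop with a consistent validation error class
.valErr <- function(...) {
  stop(errorCondition(paste0(...), class = c("imprintASE_validation", "error")))
}

.checkCount <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x != floor(x))) {
    .valErr(name, " must be non-negative integers")
  }
  invisible(TRUE)
}
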