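`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up (away from zero), the
#' convention used for all percentages reported by this package. Base R's
#' `round()` rounds half to even, which disagrees with clinical reporting
#' style on values such as 94.35.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Axis order used throughout the package: (z, y, x), 0-based voxel indices,
# boxes half-open [min, max).
AXES <- c("z", "y", "x")
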