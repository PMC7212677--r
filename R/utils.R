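#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for derived people counts and
#' presentation values. Base R's `round()` rounds half to even, which would
#' turn 8600/3 = 2866.67 into the right value but 0.5 into 0; people counts
#' in programme ledgers are conventionally rounded half-up.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(2866.5)   # 2867
#' round_half_up(4.0663, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stopifnot-style check with a readable message
.check <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.is_fraction <- function(x) .is_number(x) && x >= 0 && x <= 1
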