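#' Round half away from zero
#'
#' Commercial (half-up) rounding, as used when printing label values. Base
#' R's `round()` rounds half to even; regulatory tables round 0.05 up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the precision the
#'   claim tables print).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.25, 1)   # 2.3
#' round(2.25, 1)           # 2.2 (banker's rounding)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Round only when paper_rounding mode is on; identity otherwise.
# Computation is always performed unrounded; this is applied at the
# specific points where the printed tables round 1-decimal intermediates.
maybe_round <- function(x, paper_rounding, digits = 1) {
  if (isTRUE(paper_rounding)) round_half_up(x, digits) else x
}
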