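#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with halves always rounded up in
#' magnitude (so 93.75 -> 93.8 at one decimal), unlike [base::round()] which
#' rounds halves to even. This is the convention used by most clinical
#' reporting software.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(93.75, 1)   # 93.8
#' round_half_up(90.625, 1)  # 90.6
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Render a percentage the way the source validation report printed it
#'
#' The published performance table this package replicates was printed with an
#' effective double rounding: percentages were rounded half-up to two decimals
#' and the result rounded half-up again to one decimal. The two conventions
#' differ only when the second decimal of the raw value falls in .x45-.x49
#' (e.g. 48.148 prints as 48.2, not 48.1); the double-rounded convention
#' reproduces every cell of the published table, while plain one-decimal
#' half-up rounding misses six cells by 0.1.
#'
#' @param x Percentage values (0-100 scale).
#' @return Values rounded to one decimal under the double-rounding convention.
#' @seealso [round_half_up()] for the plain convention.
#' @export
printed_percent <- function(x) {
  round_half_up(round_half_up(x, 2), 1)
}
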