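#' Round half away from zero
#'
#' Fixed-point rounding with ties going away from zero (the convention used
#' in the published measurement tables, e.g. 49.815 -> 49.82), unlike
#' [base::round()] which rounds ties to even. A guard of 1e-9 absorbs
#' binary-representation error in values that are exact halves in decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the table convention).
#' @return `x` rounded to `digits` decimals.
#' @examples
#' round_half_up(49.815)  # 49.82
#' round(49.815, 2)       # 49.81 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# format a number at 2 decimals for reports; NA -> "-"
fmt2 <- function(x) {
  ifelse(is.na(x), "-", sprintf("%.2f", round_half_up(x, 2)))
}

# "mean ± sd" cell; sd NA (single member) prints "± n/a"
fmt_pm <- function(m, s) {
  ifelse(is.na(m), "-",
         paste0(fmt2(m), " ± ", ifelse(is.na(s), "n/a", fmt2(s))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
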