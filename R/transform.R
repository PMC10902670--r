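#' Arcsinh transform of raw ion counts
#'
#' Mass-cytometry intensities are analysed on the inverse-hyperbolic-sine
#' scale, `asinh(x / cofactor)`, with the CyTOF-conventional cofactor of 5.
#' The transform is defined for all reals and strictly monotone; negative
#' inputs (possible after bead normalisation) are accepted but flagged.
#'
#' @param x Numeric vector of raw intensities.
#' @param cofactor Positive scale divisor applied before `asinh`; default 5.
#' @return Numeric vector of transformed intensities.
#' @examples
#' arcsinh_transform(0)          # 0
#' arcsinh_transform(5)          # asinh(1) = log(1 + sqrt(2))
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("`cofactor` must be a single positive number")
  }
  if (any(x < 0, na.rm = TRUE)) {
    warning("negative raw intensities supplied to arcsinh_transform")
  }
  asinh(x / cofactor)
}

#' Format a count as a percentage of a total
#'
#' Report-style formatting used in cohort tables: `format_percent(16, 37)`
#' gives `"43.2%"`.
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 1).
#' @return Character scalar like `"43.2%"`.
#' @export
format_percent <- function(k, n, digits = 1) {
  if (n <= 0) stop("`n` must be positive")
  sprintf(paste0("%.", digits, "f%%"), round(100 * k / n, digits))
}
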