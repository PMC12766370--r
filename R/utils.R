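#' @import data.table
#' @importFrom stats quantile rbinom rlnorm rnorm rpois runif
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used for printed percentages in tabulated summaries), unlike [round()],
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @examples
#' round_half_up(22 / 71 * 100, 1)  # 31.0
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# numeric coercion that maps "" and non-numeric strings to NA without warnings
num_or_na <- function(x) suppressWarnings(as.numeric(x))

stop_faers <- function(...) stop(..., call. = FALSE)
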