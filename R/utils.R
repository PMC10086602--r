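#' Round half away from zero
#'
#' Display rounding used for every percentage and mean the pipeline reports.
#' Base R's `round()` rounds half to even; reported aggregates instead use
#' the convention where 0.25 at 1 decimal becomes 0.3.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage share, display-rounded
#'
#' @param numer,denom counts; `denom` must be positive
#' @param digits decimal places for display rounding
#' @return `100 * numer / denom`, rounded half away from zero
#' @export
pct_share <- function(numer, denom, digits = 1) {
  stopifnot(is.numeric(numer), is.numeric(denom), all(denom > 0))
  round_half_up(100 * numer / denom, digits)
}

# p-value display convention: values below the double-precision floor are
# printed as "< 2.2e-16"; the raw value is always kept alongside.
.P_DISPLAY_FLOOR <- 2.2e-16

format_p_display <- function(p) {
  ifelse(p < .P_DISPLAY_FLOOR, sprintf("< %.1e", .P_DISPLAY_FLOOR),
         sprintf("%.3g", p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, e) {
  stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
}
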