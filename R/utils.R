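# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation-layer rounding used for all reported percentages and index
#' values: exact halves round away from zero (so 10.75 -> 10.8), unlike
#' [base::round()]'s round-half-to-even. Internal computations are never
#' rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, 1.45, 86.842), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge kills binary-representation fuzz just below an exact half
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)

# "est (lo-hi)" cell used by the print methods
fmt_ci <- function(est, lo, hi, digits = 1) {
  ifelse(is.na(est), "",
         sprintf("%s (%s-%s)",
                 formatC(round_half_up(est, digits), format = "f", digits = digits),
                 formatC(round_half_up(lo, digits), format = "f", digits = digits),
                 formatC(round_half_up(hi, digits), format = "f", digits = digits)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
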