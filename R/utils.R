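# Classed conditions so callers (and the CLI) can map failures to exit codes.

parse_error <- function(...) {
  stop(structure(class = c("pooldeconv_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

usage_error <- function(...) {
  stop(structure(class = c("pooldeconv_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Round half away from zero
#'
#' Presentation rounding for reported metrics (`round()` in R rounds half
#' to even; recall/precision tables use conventional half-up rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
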