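#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.05 -> 0.1`), matching how clinical
#' papers typically render percentages, rather than base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 80.18), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a consistent classed condition
abort_hamscore <- function(msg, class) {
  stop(structure(
    class = c(class, "hamscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
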