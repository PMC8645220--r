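# internal helpers

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used when comparing
#' computed statistics against values printed at fixed precision. A small
#' epsilon absorbs binary floating-point representation error for exact
#' rational halves such as 0.675.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
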