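# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; frequency tables in the
#' cytogenetics literature are conventionally rounded half-up, so tallies and
#' rendered tables use this helper instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(0.125, 9.2431, 94.117), 2)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Valid chromosome labels: autosomes 1-22 plus X and Y.
chromosome_labels <- function() c(as.character(1:22), "X", "Y")

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == trunc(x)
}

stop_parse <- function(token, why) {
  stop(sprintf("malformed aberration token '%s': %s", token, why), call. = FALSE)
}
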