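## shared helpers: typed conditions and display rounding

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lexdens_validation_error", "lexdens_error",
                                "error", "condition")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lexdens_io_error", "lexdens_error",
                                "error", "condition")))
}

#' Round for display, half away from zero
#'
#' Reporting rounds to a fixed number of decimals with ties going away from
#' zero (so 8.475 prints as 8.48), unlike [round()]'s round-half-even.
#' All internal arithmetic keeps full precision; this is applied only when
#' numbers are shown or exported.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return numeric vector rounded to `digits` decimals.
#' @export
round_display <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
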