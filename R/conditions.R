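# Classed conditions so the CLI can map failure kinds to exit codes.

.hla_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hla_error", "error", "condition"),
    list(message = msg, call = sys.call(-2L), ...)
  ))
}

stop_parse    <- function(msg, raw = NULL) .hla_stop(msg, "hla_parse_error", raw = raw)
stop_format   <- function(msg) .hla_stop(msg, "hla_format_error")
stop_usage    <- function(msg) .hla_stop(msg, "hla_usage_error")
stop_config   <- function(msg) .hla_stop(msg, "hla_config_error")
stop_contract <- function(msg) .hla_stop(msg, "hla_contract_error")
stop_metric   <- function(msg) .hla_stop(msg, "hla_undefined_metric_error")

#' Round half away from zero
#'
#' Reporting helper: percentages are presented rounded half-up to a fixed
#' number of decimals (so 98.2456 -> 98.2, 97.26 -> 97.3), unlike base
#' [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
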