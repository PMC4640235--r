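# Structured conditions so callers (and the CLI) can map failures to
# exit codes without string matching.

mrs_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mrs_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
mrs_parameter_error <- function(message) {
  mrs_error(message, "mrs_parameter_error", call = sys.call(-1))
}

#' @noRd
mrs_validation_error <- function(message) {
  mrs_error(message, "mrs_validation_error", call = sys.call(-1))
}

#' @noRd
mrs_numerics_error <- function(message) {
  mrs_error(message, "mrs_numerics_error", call = sys.call(-1))
}

#' @noRd
mrs_io_error <- function(message) {
  mrs_error(message, "mrs_io_error", call = sys.call(-1))
}
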