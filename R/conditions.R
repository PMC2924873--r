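# Structured conditions so callers (and the CLI) can map failure kinds to
# exit codes without string-matching messages.

mirsea_error <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "mirsea_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

#' @noRd
format_error <- function(message, line = NULL) {
  if (!is.null(line)) message <- sprintf("%s (line %d)", message, line)
  mirsea_error(message, "mirsea_format_error", call = sys.call(-1), line = line)
}

validation_error <- function(message) {
  mirsea_error(message, "mirsea_validation_error", call = sys.call(-1))
}

analysis_error <- function(message) {
  mirsea_error(message, "mirsea_analysis_error", call = sys.call(-1))
}

usage_error <- function(message) {
  mirsea_error(message, "mirsea_usage_error", call = sys.call(-1))
}

invalid_identifier_error <- function(message) {
  mirsea_error(message, "mirsea_invalid_identifier", call = sys.call(-1))
}

io_error <- function(message) {
  mirsea_error(message, "mirsea_io_error", call = sys.call(-1))
}
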