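# Structured conditions so callers (and the CLI) can map failures to
# exit codes without string-matching messages.

dv_error <- function(class, msg, line_number = NULL, call. = FALSE) {
  if (!is.null(line_number)) {
    msg <- sprintf("line %d: %s", as.integer(line_number), msg)
  }
  cnd <- structure(
    class = c(class, "dosevcf_error", "error", "condition"),
    list(message = msg, call = NULL, line_number = line_number)
  )
  stop(cnd)
}

malformed_line <- function(msg, line_number = NULL) {
  dv_error("dosevcf_malformed_line", msg, line_number)
}

malformed_sample_file <- function(msg) {
  dv_error("dosevcf_malformed_sample_file", msg)
}
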