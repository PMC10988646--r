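# shared helpers: error signalling and deterministic numeric formatting

stop_mirphenet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "mirphenet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

validation_error <- function(msg, ...) stop_mirphenet(msg, "validation_error", ...)
parse_error      <- function(msg, ...) stop_mirphenet(msg, "parse_error", ...)
schema_error     <- function(msg, ...) stop_mirphenet(msg, "schema_error", ...)
usage_error      <- function(msg, ...) stop_mirphenet(msg, "usage_error", ...)

# all numeric text output uses 6 significant digits so files diff stably
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
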