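# Structured condition helpers. Two classes are distinguished so callers (and
# the CLI) can map them to exit codes: configuration problems (bad mapping,
# bad options, missing files) vs. data problems (malformed rows, duplicates).

arch_abort <- function(message, class, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "arch_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

stop_config <- function(message, ...) {
  arch_abort(message, "arch_config_error", call = sys.call(-1), ...)
}

stop_input <- function(message, ...) {
  arch_abort(message, "arch_input_error", call = sys.call(-1), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Full-precision numeric formatting: %.17g survives a write/parse round trip
# bit-exactly for finite doubles.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
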