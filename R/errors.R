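# Classed conditions so callers can distinguish bad signals from bad fits
# from bad configs without string-matching messages.

stop_grapemx <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "grapemx_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) && x <= upper
  if (!ok) {
    stop_grapemx("grapemx_config_error",
                 sprintf("`%s` must be a single number in %s%s, %s]",
                         name, if (strict_lower) "(" else "[", lower, upper))
  }
  invisible(x)
}
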