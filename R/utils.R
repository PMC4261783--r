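# Internal helpers: classed error conditions so callers and tests can
# discriminate failure modes without matching message text.

abort_odeinfer <- function(message, class) {
  stop(errorCondition(message, class = c(class, "odeinfer_error")))
}

abort_validation <- function(message) {
  abort_odeinfer(message, "odeinfer_validation_error")
}

abort_size <- function(message) {
  abort_odeinfer(message, c("odeinfer_size_error", "odeinfer_validation_error"))
}

abort_guard <- function(message) {
  abort_odeinfer(message, "odeinfer_guard_error")
}

abort_extrapolation <- function(message) {
  abort_odeinfer(message, "odeinfer_extrapolation_error")
}

abort_parse <- function(message) {
  abort_odeinfer(message, "odeinfer_parse_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    abort_validation(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  if (x != round(x))
    abort_validation(sprintf("'%s' must be a whole number", name))
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
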