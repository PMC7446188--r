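# Classed conditions so callers can distinguish failure modes by class
# rather than by message text.

rk_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "redikit_error")))
}

rk_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) rk_stop(class, msg, ...)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= min
}
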