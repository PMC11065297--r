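# Classed error conditions so callers can distinguish failure modes
# (invalid input vs. detection loss vs. degenerate data) programmatically.

stop_oomech <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "oomech_error"), call = call))
}

check_positive <- function(x, name, class = "oomech_invalid_input") {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_oomech(sprintf("`%s` must be a positive finite number", name), class)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_oomech(sprintf("`%s` must be a probability in [0, 1]", name),
                "oomech_invalid_input")
  }
  invisible(x)
}
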