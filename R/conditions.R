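# Classed error conditions so callers can distinguish engine failures.
codel_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "codel_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}
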