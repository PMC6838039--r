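# Classed error conditions so callers (and tests) can distinguish failure
# modes without matching on message text.

he_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "hestain_error")))
}

stop_invalid_input <- function(msg, ...) he_stop(msg, "he_invalid_input", ...)
stop_degenerate_stain <- function(msg, ...) he_stop(msg, "he_degenerate_stain", ...)
stop_degenerate_reference <- function(msg, ...) he_stop(msg, "he_degenerate_reference", ...)
stop_undefined_metric <- function(msg, ...) he_stop(msg, "he_undefined_metric", ...)
stop_placement <- function(msg, ...) he_stop(msg, "he_placement_error", ...)
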