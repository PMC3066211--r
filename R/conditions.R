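# Classed conditions so callers can distinguish contract violations
# (format vs validation vs numerical degeneracy) programmatically.

ks_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "kinscreen_error")))
}

stop_format      <- function(msg, ...) ks_stop("kinscreen_format_error", msg, ...)
stop_validation  <- function(msg, ...) ks_stop("kinscreen_validation_error", msg, ...)
stop_argument    <- function(msg, ...) ks_stop("kinscreen_argument_error", msg, ...)
stop_normalize   <- function(msg, ...) ks_stop("kinscreen_normalization_error", msg, ...)
stop_degenerate_trace <- function(msg, ...) ks_stop("kinscreen_degenerate_trace_error", msg, ...)
stop_degenerate_dispersion <- function(msg, ...) ks_stop("kinscreen_degenerate_dispersion_error", msg, ...)
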